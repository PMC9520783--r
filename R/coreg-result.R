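# Co-registration result: the two rigid transforms (device -> head, head ->
# MRI), the sensors expressed in the MRI frame, and the per-stage fit errors
# used for quality control.

new_coreg_result <- function(device, t1, t2, sensors_mri, fre_transform1,
                             icp_rms_transform2, icp_rms_transform1 = NULL,
                             icp_iterations = NULL, params = NULL,
                             extra = list()) {
  stopifnot(is_rigid_transform(t1), is_rigid_transform(t2))
  for (v in c(fre_transform1, icp_rms_transform1, icp_rms_transform2)) {
    if (!is.null(v) && (!is.finite(v) || v < 0)) {
      abort_input("Fit-error fields must be finite and >= 0.")
    }
  }
  structure(
    c(list(device = device,
           transform_device_to_head = t1,
           transform_head_to_mri = t2,
           transform_total = compose(t2, t1),
           sensors_mri = sensors_mri,
           fre_transform1 = fre_transform1,
           icp_rms_transform1 = icp_rms_transform1,
           icp_rms_transform2 = icp_rms_transform2,
           icp_iterations = icp_iterations,
           params = params),
      extra),
    class = "coreg_result")
}

#' @export
print.coreg_result <- function(x, ...) {
  cat(sprintf("<coreg_result> device: %s, %d channel(s) in MRI frame\n",
              x$device, nrow(x$sensors_mri)))
  print(glance(x))
  invisible(x)
}

#' Tidiers for opmcoreg objects
#'
#' `tidy()` returns the per-record view (sensors in the MRI frame for a
#' co-registration result, per-iteration RMS for an ICP fit, vertices for a
#' point cloud, centroids for a marker set); `glance()` returns a one-row
#' summary with the fit errors.
#'
#' @param x An opmcoreg result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_opmcoreg
NULL

#' @rdname tidy_opmcoreg
#' @export
tidy.coreg_result <- function(x, ...) as_tibble(x$sensors_mri)

#' @rdname tidy_opmcoreg
#' @export
glance.coreg_result <- function(x, ...) {
  tibble(device = x$device,
         n_channels = nrow(x$sensors_mri),
         fre_transform1 = x$fre_transform1,
         icp_rms_transform1 = x$icp_rms_transform1 %||% NA_real_,
         icp_rms_transform2 = x$icp_rms_transform2)
}

# Empirical quality bounds for the ICP fitting error (mm): face-surface fits
# above 2 mm and helmet fits above 0.8 mm indicate poor scan/digitization
# quality and trigger a reported warning.
FACE_RMS_WARN <- 2
HELMET_RMS_WARN <- 0.8

#' Report a co-registration result
#'
#' Prints a human-readable summary of the device, per-stage registration
#' errors and ICP iteration counts, and emits a warning when the face-surface
#' ICP RMS exceeds 2 mm or the helmet ICP RMS exceeds 0.8 mm — empirical
#' quality bounds beyond which the scanned or digitized data should be
#' checked.
#'
#' @param result A `coreg_result`.
#' @return The result, invisibly.
#' @export
report <- function(result) {
  stopifnot(inherits(result, "coreg_result"))
  cat(sprintf("Co-registration report (device: %s)\n", result$device))
  cat(sprintf("  channels mapped to MRI frame : %d\n", nrow(result$sensors_mri)))
  cat(sprintf("  transform 1 FRE              : %.4f mm\n", result$fre_transform1))
  if (!is.null(result$icp_rms_transform1)) {
    cat(sprintf("  transform 1 helmet ICP RMS   : %.4f mm\n",
                result$icp_rms_transform1))
  }
  cat(sprintf("  transform 2 face ICP RMS     : %.4f mm\n",
              result$icp_rms_transform2))
  if (!is.null(result$icp_iterations)) {
    cat(sprintf("  ICP iterations               : %s\n",
                paste(unlist(result$icp_iterations), collapse = ", ")))
  }
  if (result$icp_rms_transform2 > FACE_RMS_WARN) {
    warn(sprintf(
      "Face ICP RMS %.2f mm exceeds the %.1f mm quality bound; check the scanned or digitized data quality.",
      result$icp_rms_transform2, FACE_RMS_WARN))
  }
  if (!is.null(result$icp_rms_transform1) &&
      result$icp_rms_transform1 > HELMET_RMS_WARN) {
    warn(sprintf(
      "Helmet ICP RMS %.2f mm exceeds the %.1f mm quality bound; check the scan quality.",
      result$icp_rms_transform1, HELMET_RMS_WARN))
  }
  invisible(result)
}

#' Write a co-registration result to disk
#'
#' Writes (a) the co-registered sensor table in the MRI frame (`<prefix>_sensors_mri.csv`,
#' same schema as [read_sensor_table()]) and (b) a JSON sidecar
#' (`<prefix>_coreg.json`) with both transforms as 4 x 4 homogeneous matrices,
#' the fit errors, the device tag, parameters, and a timestamp.
#'
#' @param result A `coreg_result`.
#' @param prefix Output path prefix (directory must exist).
#' @return Invisibly, the two paths written.
#' @export
write_coreg_result <- function(result, prefix) {
  stopifnot(inherits(result, "coreg_result"))
  sensor_path <- paste0(prefix, "_sensors_mri.csv")
  meta_path <- paste0(prefix, "_coreg.json")
  write_sensor_table(result$sensors_mri, sensor_path)
  meta <- list(
    device = result$device,
    transform_device_to_head = as_homogeneous(result$transform_device_to_head),
    transform_head_to_mri = as_homogeneous(result$transform_head_to_mri),
    fre_transform1_mm = result$fre_transform1,
    icp_rms_transform1_mm = result$icp_rms_transform1,
    icp_rms_transform2_mm = result$icp_rms_transform2,
    icp_iterations = result$icp_iterations,
    parameters = if (!is.null(result$params)) unclass(result$params),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    units = "mm")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(c(sensor_path, meta_path))
}

#' Read a co-registration result back from disk
#'
#' Reconstructs the sensor array and both rigid transforms written by
#' [write_coreg_result()].
#'
#' @param prefix The prefix passed to [write_coreg_result()].
#' @return A `coreg_result`.
#' @export
read_coreg_result <- function(prefix) {
  sensor_path <- paste0(prefix, "_sensors_mri.csv")
  meta_path <- paste0(prefix, "_coreg.json")
  for (p in c(sensor_path, meta_path)) {
    if (!file.exists(p)) abort_input(sprintf("File not found: %s", p))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  t1 <- from_homogeneous(meta$transform_device_to_head, from = "device", to = "head")
  t2 <- from_homogeneous(meta$transform_head_to_mri, from = "head", to = "mri")
  new_coreg_result(
    device = meta$device, t1 = t1, t2 = t2,
    sensors_mri = read_sensor_table(sensor_path),
    fre_transform1 = meta$fre_transform1_mm,
    icp_rms_transform1 = meta$icp_rms_transform1_mm,
    icp_rms_transform2 = meta$icp_rms_transform2_mm,
    icp_iterations = meta$icp_iterations,
    params = meta$parameters)
}
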