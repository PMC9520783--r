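# Device workflows: each pipeline builds the head frame, estimates Transform 1
# (device -> head) and Transform 2 (head -> MRI), and maps the sensor array
# into the MRI frame by their composition.

head_frame_from_fiducials <- function(fiducials, from) {
  f <- as_xyz(fiducials[, c("x", "y", "z")], "fiducials")
  build_head_frame(f[1, ], f[2, ], f[3, ], from = from)
}

#' Co-register with the electromagnetic stylus digitizer
#'
#' The stylus workflow: (1) the head frame is built from the digitized
#' fiducials and every digitized point is re-expressed in it; (2) Transform 1
#' aligns the designed helmet reference points onto the digitized helmet
#' reference points by label (Kabsch; FRE recorded); (3) Transform 2
#' registers the digitized scalp points onto the MRI scalp surface by trimmed
#' ICP, seeded from a fiducial pre-alignment when `mri_fiducials` is given
#' (otherwise identity — adequate when the head and MRI frames are roughly
#' aligned); (4) sensors are mapped by the composed transform.
#'
#' @param sensors A [sensor_array()] in the device frame.
#' @param designed_refs Data frame `label, x, y, z`: designed helmet
#'   reference points (device frame).
#' @param digitized A [digitized_points()] object (digitizer frame).
#' @param mri_scalp The segmented MRI scalp surface, a [point_cloud()].
#' @param params An [icp_params()].
#' @param mri_fiducials Optional data frame `label, x, y, z` with
#'   nasion/lpa/rpa in the MRI frame, used to initialize the scalp ICP.
#' @return A `coreg_result`.
#' @export
run_fastrak <- function(sensors, designed_refs, digitized, mri_scalp,
                        params = icp_params(), mri_fiducials = NULL) {
  sensors <- sensor_array(sensors)
  stopifnot(inherits(digitized, "digitized_points"), is_point_cloud(mri_scalp))
  designed_refs <- as_tibble(designed_refs)
  if (!all(c("label", "x", "y", "z") %in% names(designed_refs))) {
    abort_input("`designed_refs` must have columns label, x, y, z.")
  }
  common <- intersect(designed_refs$label, digitized$helmet_refs$label)
  if (length(common) < 3) {
    abort_input(sprintf(
      "Need >= 3 helmet reference labels shared between design and digitization (found %d).",
      length(common)))
  }
  hf <- head_frame_from_fiducials(digitized$fiducials, from = "digitizer")
  refs_head <- transform_points(
    as_xyz(digitized$helmet_refs[match(common, digitized$helmet_refs$label),
                                 c("x", "y", "z")], "helmet refs"), hf)
  scalp_head <- transform_points(as_xyz(digitized$scalp_points, "scalp"), hf)
  fid_head <- transform_points(
    as_xyz(digitized$fiducials[, c("x", "y", "z")], "fiducials"), hf)

  fit1 <- kabsch_align(
    as_xyz(designed_refs[match(common, designed_refs$label), c("x", "y", "z")],
           "designed refs"),
    refs_head, from = "device", to = "head")

  init <- if (!is.null(mri_fiducials)) {
    mri_fiducials <- as_tibble(mri_fiducials)
    mri_fiducials$label <- tolower(as.character(mri_fiducials$label))
    ord <- match(FIDUCIAL_LABELS, mri_fiducials$label)
    if (anyNA(ord)) abort_input("`mri_fiducials` must contain nasion, lpa, rpa.")
    kabsch_align(fid_head,
                 as_xyz(mri_fiducials[ord, c("x", "y", "z")], "mri fiducials"),
                 from = "head", to = "mri")$transform
  } else {
    rigid_transform(from = "head", to = "mri")
  }
  icp2 <- icp_register(scalp_head, mri_scalp, init = init, params = params)

  new_coreg_result(
    device = "fastrak",
    t1 = fit1$transform, t2 = icp2$transform,
    sensors_mri = transform_sensors(sensors, compose(icp2$transform,
                                                     fit1$transform)),
    fre_transform1 = fit1$fre,
    icp_rms_transform2 = icp2$rms,
    icp_iterations = list(transform2 = icp2$iterations),
    params = params)
}

# Shared Transform-2 stage for the optical pipelines: coarse landmark match
# followed by face-region ICP onto the MRI scalp.
face_icp_stage <- function(scan_head, face_pairs_head, mri_scalp, params) {
  coarse <- coarse_match(face_pairs_head$source, face_pairs_head$target,
                         from = "head", to = "mri")
  icp_register(scan_head, mri_scalp, init = coarse$transform, params = params)
}

#' Co-register with a structured-light scanner
#'
#' The coloured-scan workflow: (1) the head frame is built from three picked
#' face points (nasion/left/right order) and the scan is re-expressed in it;
#' (2) Transform 1 extracts the helmet reference markers by HSV colour
#' selection and spatial clustering, then matches them to the designed
#' reference points by exhaustive permutation search (Kabsch FRE recorded);
#' (3) Transform 2 is a coarse landmark-pair match followed by trimmed ICP of
#' the cropped face region onto the MRI scalp; (4) sensors are mapped by the
#' composed transform.
#'
#' @inheritParams run_fastrak
#' @param scan The coloured scan, a [point_cloud()] in the scanner frame.
#' @param face_picks 3 x 3 matrix (or data frame) of picked face points in
#'   the scanner frame, in nasion/left/right order.
#' @param hsv An [hsv_range()] isolating the marker colour.
#' @param coarse_pairs List with `source` (K x 3, scanner frame) and `target`
#'   (K x 3, MRI frame), K >= 4 corresponding picked points.
#' @param face_region A [region_selection()] into `scan` limiting the ICP to
#'   the face area.
#' @param linkage_radius,min_cluster_size Marker clustering parameters
#'   (see [cluster_markers()]).
#' @return A `coreg_result`.
#' @export
run_structured_light <- function(sensors, designed_refs, scan, face_picks,
                                 coarse_pairs, face_region, mri_scalp,
                                 hsv = hsv_range(), params = icp_params(),
                                 linkage_radius = 10, min_cluster_size = 5) {
  sensors <- sensor_array(sensors)
  stopifnot(is_point_cloud(scan), is_point_cloud(mri_scalp))
  if (!has_colors(scan)) {
    abort_input("Structured-light co-registration needs a coloured scan.")
  }
  designed_refs <- as_tibble(designed_refs)
  picks <- as_xyz(face_picks, "face_picks")
  if (nrow(picks) != 3) abort_input("`face_picks` must contain exactly 3 points.")
  hf <- build_head_frame(picks[1, ], picks[2, ], picks[3, ], from = "scan")
  scan_head <- transform_cloud(scan, hf)

  sel <- select_by_hsv(scan_head, hsv, "marker colour")
  markers <- cluster_markers(scan_head, sel, linkage_radius = linkage_radius,
                             min_cluster_size = min_cluster_size,
                             expected_k = nrow(designed_refs), frame = "head")
  match <- match_markers(as_xyz(designed_refs[, c("x", "y", "z")], "designed refs"),
                         markers)
  t1 <- rigid_transform(match$transform$rotation, match$transform$translation,
                        from = "device", to = "head")

  pairs_head <- list(
    source = transform_points(as_xyz(coarse_pairs$source, "coarse source"), hf),
    target = as_xyz(coarse_pairs$target, "coarse target"))
  icp2 <- face_icp_stage(crop_region(scan_head, face_region), pairs_head,
                         mri_scalp, params)

  new_coreg_result(
    device = "structured_light",
    t1 = t1, t2 = icp2$transform,
    sensors_mri = transform_sensors(sensors, compose(icp2$transform, t1)),
    fre_transform1 = match$fre,
    icp_rms_transform2 = icp2$rms,
    icp_iterations = list(transform2 = icp2$iterations),
    params = params,
    extra = list(marker_permutation = match$permutation))
}

#' Co-register with a laser scanner
#'
#' The colourless high-accuracy scan workflow: (1) the head frame is built
#' from three picked face points and the scan re-expressed in it; (2)
#' Transform 1 registers the designed helmet mesh onto the scanned helmet
#' region — coarse landmark-pair match, then trimmed ICP; its RMS is recorded
#' as the helmet match error; (3) Transform 2 is the same face-region ICP
#' onto the MRI scalp as in the structured-light workflow; (4) sensors are
#' mapped by the composed transform.
#'
#' @inheritParams run_structured_light
#' @param scan The laser scan, a [point_cloud()] in the scanner frame
#'   (colours, if any, are ignored).
#' @param designed_helmet The designed helmet surface, a [point_cloud()] in
#'   the device frame.
#' @param helmet_pairs List with `source` (K x 3, device frame) and `target`
#'   (K x 3, scanner frame), K >= 4 corresponding picked points on the
#'   helmet.
#' @param helmet_region A [region_selection()] into `scan` limiting the
#'   helmet ICP to the scanned helmet.
#' @param face_pairs As `coarse_pairs` in [run_structured_light()].
#' @return A `coreg_result` (with `icp_rms_transform1`, the helmet match
#'   error).
#' @export
run_laser <- function(sensors, designed_helmet, scan, face_picks,
                      helmet_pairs, helmet_region, face_pairs, face_region,
                      mri_scalp, params = icp_params()) {
  sensors <- sensor_array(sensors)
  stopifnot(is_point_cloud(scan), is_point_cloud(mri_scalp),
            is_point_cloud(designed_helmet))
  picks <- as_xyz(face_picks, "face_picks")
  if (nrow(picks) != 3) abort_input("`face_picks` must contain exactly 3 points.")
  hf <- build_head_frame(picks[1, ], picks[2, ], picks[3, ], from = "scan")
  scan_head <- transform_cloud(scan, hf)

  coarse1 <- coarse_match(
    as_xyz(helmet_pairs$source, "helmet pairs source"),
    transform_points(as_xyz(helmet_pairs$target, "helmet pairs target"), hf),
    from = "device", to = "head")
  icp1 <- icp_register(designed_helmet, crop_region(scan_head, helmet_region),
                       init = coarse1$transform, params = params)

  pairs_head <- list(
    source = transform_points(as_xyz(face_pairs$source, "face pairs source"), hf),
    target = as_xyz(face_pairs$target, "face pairs target"))
  icp2 <- face_icp_stage(crop_region(scan_head, face_region), pairs_head,
                         mri_scalp, params)

  new_coreg_result(
    device = "laser",
    t1 = icp1$transform, t2 = icp2$transform,
    sensors_mri = transform_sensors(sensors, compose(icp2$transform,
                                                     icp1$transform)),
    fre_transform1 = coarse1$fre,
    icp_rms_transform1 = icp1$rms,
    icp_rms_transform2 = icp2$rms,
    icp_iterations = list(transform1 = icp1$iterations,
                          transform2 = icp2$iterations),
    params = params)
}
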