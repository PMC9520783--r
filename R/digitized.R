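# Digitized point sets from the electromagnetic stylus workflow: anatomical
# fiducials, free scalp points, and labelled helmet reference points, all in
# the digitizer's transmitter-fixed frame.

FIDUCIAL_LABELS <- c("nasion", "lpa", "rpa")

#' Digitized points (stylus workflow)
#'
#' Bundles the three anatomical fiducials (nasion, left/right pre-auricular
#' points), the free digitized scalp points used for scalp-surface ICP, and
#' the labelled helmet reference points used for the device-to-head alignment.
#' Fewer than 20 scalp points triggers a warning (sparse sets make the scalp
#' ICP unstable).
#'
#' @param fiducials Data frame with columns `label`, `x`, `y`, `z` containing
#'   exactly the labels nasion/lpa/rpa (case-insensitive).
#' @param scalp_points N x 3 matrix or data frame (x/y/z) of scalp samples.
#' @param helmet_refs Data frame with columns `label`, `x`, `y`, `z` of
#'   digitized helmet reference points.
#' @return An object of class `digitized_points`.
#' @export
digitized_points <- function(fiducials, scalp_points, helmet_refs) {
  fiducials <- as_tibble(fiducials)
  if (!all(c("label", "x", "y", "z") %in% names(fiducials))) {
    abort_input("`fiducials` must have columns label, x, y, z.")
  }
  fiducials$label <- tolower(as.character(fiducials$label))
  if (anyDuplicated(fiducials$label)) {
    abort_input("Duplicate fiducial labels.")
  }
  missing <- setdiff(FIDUCIAL_LABELS, fiducials$label)
  if (length(missing) > 0) {
    abort_input(sprintf("Missing fiducial(s): %s.", paste(missing, collapse = ", ")))
  }
  fiducials <- fiducials[match(FIDUCIAL_LABELS, fiducials$label),
                         c("label", "x", "y", "z")]
  as_xyz(fiducials, "fiducials")
  sp <- as_xyz(scalp_points, "scalp_points")
  if (nrow(sp) < 20) {
    warn(sprintf("Only %d scalp points; >= 20 are recommended for a stable scalp ICP.",
                 nrow(sp)))
  }
  helmet_refs <- as_tibble(helmet_refs)
  if (!all(c("label", "x", "y", "z") %in% names(helmet_refs))) {
    abort_input("`helmet_refs` must have columns label, x, y, z.")
  }
  helmet_refs$label <- as.character(helmet_refs$label)
  as_xyz(helmet_refs, "helmet_refs")
  structure(list(fiducials = fiducials, scalp_points = xyz_tibble(sp),
                 helmet_refs = helmet_refs[, c("label", "x", "y", "z")]),
            class = "digitized_points")
}

#' @export
print.digitized_points <- function(x, ...) {
  cat(sprintf("<digitized_points> 3 fiducials, %d scalp points, %d helmet refs\n",
              nrow(x$scalp_points), nrow(x$helmet_refs)))
  invisible(x)
}

#' Read digitized head and helmet-reference point tables
#'
#' Reads the stylus exports: a head-points table whose rows labelled
#' nasion/lpa/rpa (case-insensitive) become the fiducials while the remaining
#' rows become free scalp points, and a helmet reference-point table kept in
#' file order.
#'
#' @param head_path CSV with columns `label`, `x`, `y`, `z` (head points).
#' @param helmet_ref_path CSV with columns `label`, `x`, `y`, `z` (helmet
#'   reference points).
#' @return A [digitized_points()] object.
#' @export
read_digitized_points <- function(head_path, helmet_ref_path) {
  for (p in c(head_path, helmet_ref_path)) {
    if (!file.exists(p)) abort_input(sprintf("File not found: %s", p))
  }
  head <- as_tibble(utils::read.csv(head_path, stringsAsFactors = FALSE))
  refs <- as_tibble(utils::read.csv(helmet_ref_path, stringsAsFactors = FALSE))
  names(head) <- tolower(names(head))
  names(refs) <- tolower(names(refs))
  if (!all(c("label", "x", "y", "z") %in% names(head))) {
    abort_format("Head-points table must have columns label, x, y, z.")
  }
  is_fid <- tolower(head$label) %in% FIDUCIAL_LABELS
  digitized_points(fiducials = head[is_fid, ],
                   scalp_points = head[!is_fid, c("x", "y", "z")],
                   helmet_refs = refs)
}

#' Write digitized points to head/helmet CSV tables
#'
#' Inverse of [read_digitized_points()].
#'
#' @param digitized A [digitized_points()] object.
#' @param head_path,helmet_ref_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_digitized_points <- function(digitized, head_path, helmet_ref_path) {
  stopifnot(inherits(digitized, "digitized_points"))
  sp <- digitized$scalp_points
  head <- rbind(as.data.frame(digitized$fiducials),
                data.frame(label = sprintf("scalp%03d", seq_len(nrow(sp))),
                           x = sp$x, y = sp$y, z = sp$z))
  utils::write.csv(head, head_path, row.names = FALSE)
  utils::write.csv(as.data.frame(digitized$helmet_refs), helmet_ref_path,
                   row.names = FALSE)
  invisible(c(head_path, helmet_ref_path))
}
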