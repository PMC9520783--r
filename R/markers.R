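# Helmet reference-marker extraction from coloured structured-light scans:
# HSV colour thresholding, single-linkage spatial clustering into marker
# patches, and exhaustive-permutation correspondence matching against the
# designed reference points.

#' HSV colour window
#'
#' A closed box in HSV space used to select coloured marker vertices. All
#' components are on a 0–1 scale (hue included). The default window selects
#' green markers: H 0.2–0.66, S 0.3–1, V 0.16–1. Hue intervals must not wrap
#' around 0/1; split a wrapping window (e.g. red) into two ranges and combine
#' the selections.
#'
#' @param h,s,v Length-2 numeric `c(min, max)` in `[0, 1]` with `min <= max`.
#' @return An object of class `hsv_range`.
#' @export
hsv_range <- function(h = c(0.2, 0.66), s = c(0.3, 1), v = c(0.16, 1)) {
  for (nm in c("h", "s", "v")) {
    rng <- get(nm)
    if (!is.numeric(rng) || length(rng) != 2 || anyNA(rng) ||
        rng[1] > rng[2] || rng[1] < 0 || rng[2] > 1) {
      abort_input(sprintf("`%s` must be c(min, max) within [0, 1], min <= max.", nm))
    }
  }
  structure(list(h = as.numeric(h), s = as.numeric(s), v = as.numeric(v)),
            class = "hsv_range")
}

#' Convert RGB colours to HSV
#'
#' Standard hexagonal-cone conversion with all three channels on a 0–1 scale
#' (hue in `[0, 1)`). Thin wrapper over [grDevices::rgb2hsv()] for tabular
#' input.
#'
#' @param rgb N x 3 matrix or data frame (r/g/b columns) with values in
#'   `[0, 255]`.
#' @return A tibble with columns `h`, `s`, `v` in `[0, 1]`.
#' @examples
#' rgb_to_hsv(rbind(c(0, 255, 0)))  # pure green: h = 1/3, s = 1, v = 1
#' @export
rgb_to_hsv <- function(rgb) {
  if (is.data.frame(rgb)) {
    if (!all(c("r", "g", "b") %in% names(rgb))) {
      abort_input("`rgb` data frame must have columns r, g, b.")
    }
    rgb <- cbind(rgb$r, rgb$g, rgb$b)
  }
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3 || !is.numeric(rgb)) {
    abort_input("`rgb` must be an N x 3 numeric matrix.")
  }
  if (!all(is.finite(rgb)) || min(rgb) < 0 || max(rgb) > 255) {
    abort_input("RGB values must lie in [0, 255].")
  }
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  tibble(h = hsv[1, ] %% 1, s = hsv[2, ], v = hsv[3, ])
}

#' Select vertices by HSV colour window
#'
#' Selects every vertex of a coloured point cloud whose colour falls inside
#' the closed HSV box — the colour-extraction step that isolates painted
#' helmet reference markers in a structured-light scan.
#'
#' @param cloud A coloured [point_cloud()].
#' @param range An [hsv_range()].
#' @param description Optional selection description.
#' @return A [region_selection()] of the matching vertices.
#' @export
select_by_hsv <- function(cloud, range = hsv_range(),
                          description = "HSV colour selection") {
  stopifnot(is_point_cloud(cloud), inherits(range, "hsv_range"))
  if (!has_colors(cloud)) {
    abort_input("Cloud has no per-vertex colours; HSV selection needs a coloured scan.")
  }
  hsv <- rgb_to_hsv(cloud$vertices[, c("r", "g", "b")])
  inside <- hsv$h >= range$h[1] & hsv$h <= range$h[2] &
    hsv$s >= range$s[1] & hsv$s <= range$s[2] &
    hsv$v >= range$v[1] & hsv$v <= range$v[2]
  idx <- which(inside)
  if (length(idx) == 0) {
    abort_marker_count("No vertices fall inside the HSV window; check marker colour and window.")
  }
  region_selection(idx, description)
}

#' Cluster selected vertices into marker patches
#'
#' Groups the colour-selected vertices into connected components under
#' "within `linkage_radius`" adjacency (single-linkage clustering cut at the
#' linkage radius), drops components smaller than `min_cluster_size`, and
#' returns component centroids. Errors unless exactly `expected_k` markers
#' survive, reporting the per-cluster sizes for diagnosis.
#'
#' @param cloud A [point_cloud()].
#' @param selection A [region_selection()] (e.g. from [select_by_hsv()]).
#' @param linkage_radius Adjacency radius (mm); default 10.
#' @param min_cluster_size Minimum vertices per marker patch; default 5.
#' @param expected_k Number of markers that must be found.
#' @return An object of class `marker_set`: tibble `centroids` (x, y, z, n)
#'   and `frame`.
#' @export
cluster_markers <- function(cloud, selection, linkage_radius = 10,
                            min_cluster_size = 5, expected_k,
                            frame = NULL) {
  stopifnot(is_point_cloud(cloud), inherits(selection, "region_selection"))
  if (!is.numeric(linkage_radius) || linkage_radius <= 0) {
    abort_input("`linkage_radius` must be positive (mm).")
  }
  if (max(selection$indices) > n_vertices(cloud)) {
    abort_input("Selection indexes beyond the cloud's vertex count.")
  }
  pts <- cloud_xyz(cloud)[selection$indices, , drop = FALSE]
  n <- nrow(pts)
  labels <- if (n == 1) {
    1L
  } else {
    cutree(hclust(dist(pts), method = "single"), h = linkage_radius)
  }
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_cluster_size)
  k <- length(keep)
  if (k != expected_k) {
    abort_marker_count(sprintf(
      paste0("Expected %d markers but found %d cluster(s) of size >= %d ",
             "(all cluster sizes: %s). Adjust the HSV window, linkage radius, ",
             "or minimum cluster size."),
      expected_k, k, min_cluster_size,
      paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  }
  cent <- t(vapply(keep, function(cl) colMeans(pts[labels == cl, , drop = FALSE]),
                   numeric(3)))
  centroids <- xyz_tibble(cent)
  centroids$n <- sizes[keep]
  structure(list(centroids = centroids, frame = check_frame_tag(frame, "frame")),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers%s\n", nrow(x$centroids),
              if (!is.null(x$frame)) paste0(" [", x$frame, "]") else ""))
  print(x$centroids)
  invisible(x)
}

#' @rdname tidy_opmcoreg
#' @export
tidy.marker_set <- function(x, ...) x$centroids

#' Match detected markers to designed reference points
#'
#' Finds the correspondence between detected marker centroids and the
#' designed helmet reference points by exhaustive search over all K!
#' assignments, Kabsch-fitting each and keeping the assignment with the
#' smallest FRE. The result is rejected as ambiguous when the runner-up
#' assignment's FRE comes within `ambiguity_factor` of the best (as happens
#' for symmetric marker layouts such as an equilateral triangle).
#'
#' @param designed K x 3 designed reference points (device frame), matrix or
#'   data frame; 3 <= K <= 8.
#' @param detected A `marker_set` (from [cluster_markers()]) or K x 3 points.
#' @param ambiguity_factor Ambiguity rejection threshold (default 2): error if
#'   `runner_up_fre <= ambiguity_factor * max(best_fre, 1e-6)`.
#' @return A list of class `marker_match`: `permutation` (detected index for
#'   each designed row), `transform` (designed frame to detected frame),
#'   `fre` (mm).
#' @export
match_markers <- function(designed, detected, ambiguity_factor = 2) {
  d <- as_xyz(designed, "designed")
  det <- if (inherits(detected, "marker_set")) {
    as_xyz(detected$centroids, "detected")
  } else {
    as_xyz(detected, "detected")
  }
  k <- nrow(d)
  if (nrow(det) != k) {
    abort_marker_count(sprintf(
      "Designed (%d) and detected (%d) marker counts differ.", k, nrow(det)))
  }
  if (k < 3) abort_input("Marker matching needs at least 3 markers.")
  if (k > 8) {
    abort(sprintf("Marker matching supports at most 8 markers (got %d).", k),
          class = c("opmcoreg_error_unsupported", "opmcoreg_error_input",
                    "opmcoreg_error"))
  }
  perms <- pracma::perms(seq_len(k))
  fits <- vector("list", nrow(perms))
  fres <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    fit <- tryCatch(kabsch_align(d, det[perms[i, ], , drop = FALSE]),
                    opmcoreg_error_degenerate = function(e) NULL)
    if (is.null(fit)) {
      fres[i] <- Inf
    } else {
      fits[[i]] <- fit
      fres[i] <- fit$fre
    }
  }
  if (!any(is.finite(fres))) {
    abort_degenerate("Designed marker layout is degenerate (collinear points).")
  }
  ord <- order(fres)
  best <- ord[1]
  runner <- ord[2]
  if (fres[runner] <= ambiguity_factor * max(fres[best], 1e-6)) {
    abort_ambiguity(sprintf(
      paste0("Marker correspondence is ambiguous: best FRE %.4g mm vs ",
             "runner-up %.4g mm. Use an asymmetric marker layout."),
      fres[best], fres[runner]))
  }
  structure(list(permutation = as.integer(perms[best, ]),
                 transform = fits[[best]]$transform, fre = fres[best]),
            class = "marker_match")
}

#' @export
print.marker_match <- function(x, ...) {
  cat(sprintf("<marker_match> permutation (%s), FRE = %.6g mm\n",
              paste(x$permutation, collapse = ", "), x$fre))
  invisible(x)
}
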