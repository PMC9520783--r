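# Diagnostic plots. 3D geometry is shown as the three axis-aligned
# projections; enough to eyeball whether sensors land on the scalp and how
# the ICP converged.

projection_data <- function(xyz, what) {
  tb <- xyz_tibble(as_xyz(xyz, "points"))
  dplyr::bind_rows(
    tibble(h = tb$x, v = tb$y, plane = "axial (x-y)", what = what),
    tibble(h = tb$x, v = tb$z, plane = "sagittal (x-z)", what = what),
    tibble(h = tb$y, v = tb$z, plane = "coronal (y-z)", what = what))
}

#' Plot a co-registration result
#'
#' Shows the co-registered sensor positions over the MRI scalp surface in the
#' three axis-aligned projections.
#'
#' @param object A `coreg_result`.
#' @param mri_scalp Optional [point_cloud()] of the MRI scalp to draw under
#'   the sensors.
#' @param max_scalp_points Scalp vertices are thinned to at most this many
#'   for plotting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coreg_result <- function(object, mri_scalp = NULL,
                                  max_scalp_points = 3000, ...) {
  dat <- projection_data(as_tibble(object$sensors_mri)[, c("x", "y", "z")],
                         "sensors (MRI frame)")
  if (!is.null(mri_scalp)) {
    v <- cloud_xyz(mri_scalp)
    if (nrow(v) > max_scalp_points) {
      v <- v[seq(1, nrow(v), length.out = max_scalp_points), , drop = FALSE]
    }
    dat <- dplyr::bind_rows(projection_data(v, "MRI scalp"), dat)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, y = .data$v,
                                    colour = .data$what)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c("sensors (MRI frame)" = "#d55e00",
                                            "MRI scalp" = "grey60")) +
    ggplot2::labs(x = "mm", y = "mm", colour = NULL,
                  title = sprintf("Co-registered sensors (%s)", object$device),
                  subtitle = sprintf("transform 1 FRE %.2f mm, face ICP RMS %.2f mm",
                                     object$fre_transform1,
                                     object$icp_rms_transform2)) +
    ggplot2::theme_minimal()
}

#' Plot ICP convergence
#'
#' Retained-pair RMS per iteration.
#'
#' @param object An `icp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icp_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$iteration, y = .data$rms)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ICP iteration", y = "retained-pair RMS (mm)",
                  title = "ICP convergence") +
    ggplot2::theme_minimal()
}

#' Plot a point cloud
#'
#' Axis-aligned projections of the vertices, coloured by the per-vertex RGB
#' when present.
#'
#' @param object A [point_cloud()].
#' @param max_points Thin to at most this many vertices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_cloud <- function(object, max_points = 5000, ...) {
  v <- object$vertices
  if (nrow(v) > max_points) {
    v <- v[seq(1, nrow(v), length.out = max_points), , drop = FALSE]
  }
  dat <- projection_data(v[, c("x", "y", "z")], "vertices")
  if (has_colors(object)) {
    col <- grDevices::rgb(v$r, v$g, v$b, maxColorValue = 255)
    dat$col <- rep(col, 3)
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, y = .data$v)) +
      ggplot2::geom_point(colour = dat$col, size = 0.5)
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$h, y = .data$v)) +
      ggplot2::geom_point(size = 0.5, colour = "grey30")
  }
  p + ggplot2::facet_wrap(~plane, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
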