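# Sensor arrays: per-channel label, vapor-cell position (mm), and one or more
# unit orientation vectors (K = 1 radial single-axis, K = 3 tri-axis). The
# tabular form is a tibble with columns label, x, y, z, ox1, oy1, oz1,
# [ox2, ..., oz3]; ox/oy/oz is accepted as a K = 1 alias on input.

orientation_cols <- function(k) {
  as.vector(vapply(seq_len(k), function(i) {
    paste0(c("ox", "oy", "oz"), i)
  }, character(3)))
}

#' Sensor array
#'
#' Validates and classes a sensor table: unique channel labels, finite
#' positions (mm), and K >= 1 orientation triplets per channel, each
#' renormalized to exactly unit norm. A row's orientation norm deviating more
#' than 0.05 from 1 before renormalization triggers a warning; a near-zero
#' norm is an error.
#'
#' @param x A data frame with columns `label`, `x`, `y`, `z`, and orientation
#'   columns `ox1, oy1, oz1, ...` (or `ox, oy, oz` for K = 1).
#' @return A tibble of class `sensor_array` with normalized orientation
#'   columns `ox1...ozK`.
#' @export
sensor_array <- function(x) {
  if (!is.data.frame(x)) abort_input("A sensor array must be a data frame.")
  x <- as_tibble(x)
  if (all(c("ox", "oy", "oz") %in% names(x)) && !"ox1" %in% names(x)) {
    names(x)[match(c("ox", "oy", "oz"), names(x))] <- c("ox1", "oy1", "oz1")
  }
  req <- c("label", "x", "y", "z")
  if (!all(req %in% names(x))) {
    abort_input("Sensor table must have columns label, x, y, z.")
  }
  k <- 0L
  while (all(orientation_cols(k + 1L)[3 * k + 1:3] %in% names(x))) k <- k + 1L
  if (k < 1) {
    abort_input("Sensor table must have at least one orientation triplet (ox1, oy1, oz1).")
  }
  x$label <- as.character(x$label)
  if (anyDuplicated(x$label)) abort_input("Sensor labels must be unique.")
  pos <- as_xyz(x[, c("x", "y", "z")], "sensor positions")
  for (i in seq_len(k)) {
    cols <- orientation_cols(k)[3 * (i - 1) + 1:3]
    o <- as.matrix(x[, cols])
    if (!all(is.finite(o))) abort_input("Sensor orientations contain non-finite values.")
    nrm <- sqrt(rowSums(o^2))
    if (any(nrm < 1e-6)) {
      abort_input("Sensor orientation with near-zero norm; orientations must be directions.")
    }
    if (any(abs(nrm - 1) > 0.05)) {
      warn(sprintf(
        "Orientation triplet %d has norms deviating > 0.05 from 1 (worst %.3f); renormalizing.",
        i, nrm[which.max(abs(nrm - 1))]))
    }
    x[, cols] <- o / nrm
  }
  keep <- c("label", "x", "y", "z", orientation_cols(k))
  x <- x[, c(keep, setdiff(names(x), keep))]
  class(x) <- c("sensor_array", "tbl_df", "tbl", "data.frame")
  x
}

#' @export
is_sensor_array <- function(x) inherits(x, "sensor_array")

#' Number of orientation axes per channel
#'
#' @param sensors A [sensor_array()] (1 for radial single-axis OPMs, 3 for
#'   tri-axis).
#' @export
n_axes <- function(sensors) {
  k <- 0L
  while (all(orientation_cols(k + 1L)[3 * k + 1:3] %in% names(sensors))) k <- k + 1L
  k
}

#' Read a sensor table
#'
#' Reads a delimited sensor table with header `label, px, py, pz, ox1, oy1,
#' oz1, ...` (or `x, y, z` / `ox, oy, oz` aliases); K is inferred from the
#' orientation columns.
#'
#' @param path Path to a CSV file.
#' @return A [sensor_array()].
#' @export
read_sensor_table <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("Sensor table not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  alias <- c(px = "x", py = "y", pz = "z")
  hit <- names(x) %in% names(alias)
  names(x)[hit] <- alias[names(x)[hit]]
  sensor_array(x)
}

#' Write a sensor table
#'
#' Writes the same schema [read_sensor_table()] reads.
#'
#' @param sensors A [sensor_array()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sensor_table <- function(sensors, path) {
  sensors <- sensor_array(sensors)
  utils::write.csv(as.data.frame(sensors), path, row.names = FALSE)
  invisible(path)
}

#' Apply a rigid transform to a sensor array
#'
#' Positions are mapped by the full transform, orientation vectors by its
#' rotation only; orientation unit norms are preserved exactly.
#'
#' @param sensors A [sensor_array()].
#' @param transform A [rigid_transform()].
#' @return The transformed [sensor_array()].
#' @export
transform_sensors <- function(sensors, transform) {
  sensors <- sensor_array(sensors)
  k <- n_axes(sensors)
  pos <- transform_points(as_xyz(sensors[, c("x", "y", "z")]), transform)
  sensors$x <- pos[, 1]; sensors$y <- pos[, 2]; sensors$z <- pos[, 3]
  for (i in seq_len(k)) {
    cols <- orientation_cols(k)[3 * (i - 1) + 1:3]
    o <- transform_directions(as.matrix(sensors[, cols]), transform)
    sensors[, cols] <- o
  }
  sensors
}

#' Select channels and apply sensor-depth correction
#'
#' Keeps only the selected channels and moves each one along its radial
#' orientation by its insertion depth. The depth of a channel is either given
#' directly (`depth`, mm) or derived from the measured triple as
#' `depth = l - t - h`, where `l` is the sensor height, `t` the helmet
#' thickness, and `h` the height of the sensor left exposed outside the
#' helmet (all mm). Flush insertion (`h = l - t`) gives depth 0 and leaves the
#' position unchanged.
#'
#' Sign convention: stored orientations point inward (helmet towards scalp),
#' so positive depth moves the sensor closer to the scalp. Set
#' `flip_direction = TRUE` if your orientations point outward. For tri-axis
#' arrays the first orientation triplet is taken as the radial axis.
#' Orientations are never modified.
#'
#' @param sensors A [sensor_array()].
#' @param channels Character vector of channel labels to keep (subset of the
#'   array's labels), or a data frame with a `label` column.
#' @param depths A data frame with column `label` and either `depth` or the
#'   triple `l`, `t`, `h` (mm); must cover every selected channel.
#' @param flip_direction If `TRUE`, positive depth moves against the stored
#'   orientation.
#' @return A [sensor_array()] containing only the selected channels, with
#'   depth-corrected positions.
#' @examples
#' sens <- sensor_array(tibble::tibble(label = "A1", x = 0, y = 0, z = 10,
#'                                     ox = 0, oy = 0, oz = -1))
#' depths <- tibble::tibble(label = "A1", l = 14.5, t = 3, h = 8.5)  # depth 3
#' apply_depth(sens, "A1", depths)$z  # 10 - 3
#' @export
apply_depth <- function(sensors, channels, depths, flip_direction = FALSE) {
  sensors <- sensor_array(sensors)
  if (is.data.frame(channels)) channels <- channels$label
  channels <- as.character(channels)
  if (length(channels) == 0) abort_input("Channel selection must be non-empty.")
  unknown <- setdiff(channels, sensors$label)
  if (length(unknown) > 0) {
    abort_input(sprintf("Unknown channel label(s): %s.",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.data.frame(depths) || !"label" %in% names(depths)) {
    abort_input("`depths` must be a data frame with a `label` column.")
  }
  depths <- as_tibble(depths)
  depths$label <- as.character(depths$label)
  if (anyDuplicated(depths$label)) abort_input("Duplicate labels in `depths`.")
  if ("depth" %in% names(depths)) {
    dvals <- depths$depth
  } else if (all(c("l", "t", "h") %in% names(depths))) {
    if (any(depths$l <= 0) || any(depths$t < 0) || any(depths$h < 0)) {
      abort_input("Depth triple requires l > 0, t >= 0, h >= 0 (mm).")
    }
    dvals <- depths$l - depths$t - depths$h
  } else {
    abort_input("`depths` must have either a `depth` column or the triple l, t, h.")
  }
  missing <- setdiff(channels, depths$label)
  if (length(missing) > 0) {
    abort_input(sprintf("No depth given for selected channel(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  d <- dvals[match(channels, depths$label)]
  if (any(abs(d) > 50)) {
    warn(sprintf("Implausible sensor depth |%.1f| mm > 50 mm; check l/t/h measurements.",
                 d[which.max(abs(d))]))
  }
  out <- sensors[match(channels, sensors$label), , drop = FALSE]
  k <- n_axes(sensors)
  radial <- unname(as.matrix(out[, orientation_cols(k)[1:3]]))
  sgn <- if (flip_direction) -1 else 1
  out$x <- out$x + sgn * d * radial[, 1]
  out$y <- out$y + sgn * d * radial[, 2]
  out$z <- out$z + sgn * d * radial[, 3]
  sensor_array(out)
}
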