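# Internal helpers shared across modules: coordinate coercion and classed
# error conditions. All condition classes carry the "opmcoreg_error" prefix so
# the CLI can map them onto exit codes.

abort_input <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_input", "opmcoreg_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_format", "opmcoreg_error_input",
                       "opmcoreg_error"), ...)
}

abort_degenerate <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_degenerate", "opmcoreg_error"), ...)
}

abort_frame <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_frame", "opmcoreg_error"), ...)
}

abort_registration <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_registration", "opmcoreg_error"), ...)
}

abort_ambiguity <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_ambiguity", "opmcoreg_error"), ...)
}

abort_marker_count <- function(msg, ...) {
  abort(msg, class = c("opmcoreg_error_marker_count", "opmcoreg_error"), ...)
}

# Coerce points to an N x 3 numeric matrix. Accepts a numeric matrix, a bare
# numeric vector of length 3, or a data frame with x/y/z columns.
as_xyz <- function(pts, arg = "points", allow_nonfinite = FALSE) {
  if (is.data.frame(pts)) {
    if (!all(c("x", "y", "z") %in% names(pts))) {
      abort_input(sprintf("`%s` data frame must have columns x, y, z.", arg))
    }
    m <- cbind(pts$x, pts$y, pts$z)
  } else if (is.numeric(pts) && is.null(dim(pts)) && length(pts) == 3) {
    m <- matrix(pts, nrow = 1)
  } else if (is.matrix(pts) && is.numeric(pts)) {
    if (ncol(pts) != 3) {
      abort_input(sprintf("`%s` must be an N x 3 matrix.", arg))
    }
    m <- pts
  } else {
    abort_input(sprintf(
      "`%s` must be an N x 3 numeric matrix, a length-3 vector, or a data frame with x/y/z.",
      arg))
  }
  storage.mode(m) <- "double"
  if (!allow_nonfinite && !all(is.finite(m))) {
    abort_input(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  dimnames(m) <- NULL
  m
}

xyz_tibble <- function(m) {
  tibble(x = m[, 1], y = m[, 2], z = m[, 3])
}

# Return transformed coordinates in the same container type the caller used.
restore_points_type <- function(m, template) {
  if (is.data.frame(template)) {
    out <- as_tibble(template)
    out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
    out
  } else if (is.null(dim(template)) && length(template) == 3) {
    drop(m)
  } else {
    m
  }
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort_degenerate(sprintf("Cannot normalize zero-length %s.", what))
  v / n
}
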