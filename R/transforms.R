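# Rigid-body mathematics: proper rigid transforms (rotation + translation in
# millimetres), Kabsch least-squares alignment, composition/inversion, and
# head-frame construction from anatomical fiducials.

FRAME_TAGS <- c("device", "digitizer", "scan", "head", "mri")

check_frame_tag <- function(tag, arg) {
  if (is.null(tag)) return(NULL)
  tag <- as.character(tag)
  if (length(tag) != 1 || !tag %in% FRAME_TAGS) {
    abort_frame(sprintf("`%s` must be one of: %s.", arg,
                        paste(FRAME_TAGS, collapse = ", ")))
  }
  tag
}

#' Rigid transform (rotation + translation)
#'
#' Constructs a proper rigid transform mapping points `p` to `R p + t`.
#' Rotations must be orthonormal with determinant +1 (no reflection, no
#' scaling); translations are in millimetres. Transforms optionally carry
#' source/target frame tags (`device`, `digitizer`, `scan`, `head`, `mri`)
#' which are checked on composition and propagated through pipelines.
#'
#' @param rotation 3 x 3 orthonormal rotation matrix with `det = +1`.
#' @param translation Numeric length-3 translation vector (mm).
#' @param from,to Optional frame tags recording the source and target
#'   coordinate systems.
#' @return An object of class `rigid_transform` with elements `rotation`,
#'   `translation`, `from`, `to`.
#' @examples
#' t1 <- rigid_transform(translation = c(10, -5, 3))
#' transform_points(c(0, 0, 0), t1)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = NULL, to = NULL) {
  rotation <- as.matrix(rotation)
  if (!is.numeric(rotation) || !all(dim(rotation) == c(3, 3)) ||
      !all(is.finite(rotation))) {
    abort_input("`rotation` must be a finite 3 x 3 numeric matrix.")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort_input("`rotation` is not orthonormal (R'R != I beyond 1e-9).")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    abort_input("`rotation` must be a proper rotation with det(R) = +1 (reflections/scaling disallowed).")
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3 || !all(is.finite(translation))) {
    abort_input("`translation` must be a finite length-3 numeric vector.")
  }
  structure(
    list(rotation = unname(rotation), translation = translation,
         from = check_frame_tag(from, "from"), to = check_frame_tag(to, "to")),
    class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  tag <- if (!is.null(x$from) || !is.null(x$to)) {
    sprintf(" [%s -> %s]", x$from %||% "?", x$to %||% "?")
  } else ""
  cat(sprintf("<rigid_transform>%s\n", tag))
  cat(sprintf("  rotation angle: %.4f deg, translation: (%.3f, %.3f, %.3f) mm\n",
              rotation_angle(x) * 180 / pi,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Rotation angle of a rigid transform
#'
#' Geodesic rotation angle in radians, `acos((tr(R) - 1) / 2)`.
#'
#' @param transform A [rigid_transform()].
#' @return Angle in radians in `[0, pi]`.
#' @export
rotation_angle <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  acos(max(-1, min(1, (sum(diag(transform$rotation)) - 1) / 2)))
}

#' Align two corresponding point sets by a rigid transform (Kabsch)
#'
#' Finds the proper rigid transform minimizing the sum of squared distances
#' between transformed source points and their corresponding target points
#' (equal row indices correspond). Uses the SVD-based Kabsch solution with the
#' determinant correction so a reflection is never returned; no scaling is
#' applied. The residual is reported as the fiducial registration error (FRE),
#' the RMS distance after alignment.
#'
#' @param source,target Corresponding point sets, N x 3 (N >= 3), as matrices
#'   or data frames with x/y/z columns; in millimetres.
#' @param from,to Optional frame tags for the returned transform.
#' @return A list of class `kabsch_alignment` with elements `transform` (a
#'   [rigid_transform()]) and `fre` (RMS residual, mm).
#' @examples
#' src <- rbind(c(0, 0, 0), c(80, 0, 0), c(30, 60, 0))
#' fit <- kabsch_align(src, src + rep(c(10, -5, 3), each = 3))
#' fit$fre
#' @export
kabsch_align <- function(source, target, from = NULL, to = NULL) {
  s <- as_xyz(source, "source")
  t <- as_xyz(target, "target")
  if (nrow(s) != nrow(t)) {
    abort_input("`source` and `target` must contain the same number of points.")
  }
  if (nrow(s) < 3) {
    abort_input("At least 3 corresponding point pairs are required.")
  }
  cs <- colMeans(s)
  ct <- colMeans(t)
  s0 <- sweep(s, 2, cs)
  t0 <- sweep(t, 2, ct)
  sv <- svd(s0)
  if (sv$d[1] < 1e-12 || sv$d[2] < 1e-6 * sv$d[1]) {
    abort_degenerate("Source points are collinear or duplicated; rigid alignment is underdetermined.")
  }
  h <- crossprod(s0, t0)
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  r <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- ct - as.numeric(r %*% cs)
  resid <- t0 - s0 %*% t(r)
  fre <- sqrt(mean(rowSums(resid^2)))
  structure(
    list(transform = rigid_transform(r, tr, from = from, to = to), fre = fre,
         n = nrow(s)),
    class = "kabsch_alignment")
}

#' @export
print.kabsch_alignment <- function(x, ...) {
  cat(sprintf("<kabsch_alignment> n = %d pairs, FRE = %.6g mm\n", x$n, x$fre))
  print(x$transform)
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose(t2, t1)` returns the transform whose application equals applying
#' `t1` first and then `t2`. Frame tags, when present on both operands, must
#' chain (`t1$to == t2$from`) and are propagated.
#'
#' @param t2,t1 [rigid_transform()] objects, applied in the order `t1` then `t2`.
#' @return A [rigid_transform()].
#' @export
compose <- function(t2, t1) {
  stopifnot(is_rigid_transform(t2), is_rigid_transform(t1))
  if (!is.null(t1$to) && !is.null(t2$from) && t1$to != t2$from) {
    abort_frame(sprintf(
      "Frame mismatch in composition: t1 maps into '%s' but t2 expects '%s'.",
      t1$to, t2$from))
  }
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation,
                  from = t1$from, to = t2$to)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse transform; frame tags are swapped.
#' @export
invert <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation),
                  from = transform$to, to = transform$from)
}

#' Apply a rigid transform to points
#'
#' Maps every row by `R p + t`.
#'
#' @param points N x 3 matrix, length-3 vector, or data frame with x/y/z
#'   columns (mm).
#' @param transform A [rigid_transform()].
#' @return Transformed coordinates in the same container type as the input
#'   (tibble in, tibble out).
#' @export
transform_points <- function(points, transform) {
  stopifnot(is_rigid_transform(transform))
  m <- as_xyz(points, "points")
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  restore_points_type(out, points)
}

#' Apply a rigid transform to direction vectors
#'
#' Maps each unit direction by the rotation part only (no translation) and
#' renormalizes, so sensor orientations remain exactly unit-norm.
#'
#' @param directions N x 3 unit vectors (unit-norm to 1e-6), matrix, length-3
#'   vector, or data frame with x/y/z columns.
#' @param transform A [rigid_transform()].
#' @return Rotated unit vectors in the same container type as the input.
#' @export
transform_directions <- function(directions, transform) {
  stopifnot(is_rigid_transform(transform))
  m <- as_xyz(directions, "directions")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-6)) {
    abort_input("`directions` contains a zero-norm row.")
  }
  if (any(abs(nrm - 1) > 1e-6)) {
    abort_input("`directions` rows must be unit-norm to 1e-6.")
  }
  out <- m %*% t(transform$rotation)
  out <- out / sqrt(rowSums(out^2))
  restore_points_type(out, directions)
}

#' Build the head coordinate frame from three fiducials
#'
#' Constructs the subject-anchored MEG-Head frame in the CTF-like convention:
#' origin at the midpoint of the left and right pre-auricular points, +X
#' through the nasion, +Z up (normal to the fiducial plane, `X x dir(LPA)`),
#' and +Y completing the right-handed frame (towards the left ear). The
#' returned transform maps coordinates given in the fiducials' frame into this
#' head frame. For optical scans, three picked face points in nasion/left/right
#' order serve as pseudo-fiducials; only their ordering matters.
#'
#' @param nasion,lpa,rpa Length-3 points (mm) in a common source frame.
#' @param from Optional source frame tag (e.g. `"digitizer"`, `"scan"`).
#' @return A [rigid_transform()] mapping the source frame to `head`.
#' @examples
#' hf <- build_head_frame(c(0, 100, 0), c(-75, 0, 0), c(75, 0, 0))
#' transform_points(c(0, 100, 0), hf)  # nasion on the +X axis
#' @export
build_head_frame <- function(nasion, lpa, rpa, from = NULL) {
  nasion <- drop(as_xyz(nasion, "nasion"))
  lpa <- drop(as_xyz(lpa, "lpa"))
  rpa <- drop(as_xyz(rpa, "rpa"))
  origin <- (lpa + rpa) / 2
  xn <- nasion - origin
  le <- lpa - origin
  if (sqrt(sum(xn^2)) < 1e-9 || sqrt(sum(le^2)) < 1e-9) {
    abort_degenerate("Fiducials are coincident; cannot build a head frame.")
  }
  x <- unit3(xn, "nasion axis")
  zraw <- cross3(x, unit3(le, "ear axis"))
  if (sqrt(sum(zraw^2)) < 1e-9) {
    abort_degenerate("Fiducials are collinear; cannot build a head frame.")
  }
  z <- unit3(zraw)
  y <- cross3(z, x)
  r <- rbind(x, y, z)
  dimnames(r) <- NULL
  rigid_transform(r, -as.numeric(r %*% origin), from = from, to = "head")
}

#' Convert a rigid transform to a 4 x 4 homogeneous matrix
#'
#' @param transform A [rigid_transform()].
#' @return A 4 x 4 matrix with the rotation in the top-left block and the
#'   translation in the fourth column.
#' @export
as_homogeneous <- function(transform) {
  stopifnot(is_rigid_transform(transform))
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Build a rigid transform from a 4 x 4 homogeneous matrix
#'
#' @param m A 4 x 4 homogeneous matrix with a proper-rotation block.
#' @param from,to Optional frame tags.
#' @return A [rigid_transform()].
#' @export
from_homogeneous <- function(m, from = NULL, to = NULL) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4))) abort_input("`m` must be a 4 x 4 matrix.")
  rigid_transform(m[1:3, 1:3], m[1:3, 4], from = from, to = to)
}

# Rotation about a unit axis by angle (radians); Rodrigues formula.
rotation_about_axis <- function(axis, angle) {
  a <- unit3(as.numeric(axis), "rotation axis")
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  r <- diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
  # re-orthonormalize to keep the constructor's 1e-9 tolerance honest
  sv <- svd(r)
  sv$u %*% t(sv$v)
}

#' Random rigid transform
#'
#' Draws a rotation about a uniformly random axis and a translation with a
#' uniformly random direction. Useful for phantom ground truths and
#' property-style tests. Uses the current RNG state.
#'
#' @param max_angle Maximum rotation angle (radians); angle drawn uniformly in
#'   `[0, max_angle]`.
#' @param max_translation Maximum translation norm (mm); norm drawn uniformly
#'   in `[0, max_translation]`.
#' @param from,to Optional frame tags.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle = pi, max_translation = 200,
                                   from = NULL, to = NULL) {
  ax <- rnorm(3)
  while (sum(ax^2) < 1e-6) ax <- rnorm(3)
  ang <- runif(1, 0, max_angle)
  dir <- rnorm(3)
  while (sum(dir^2) < 1e-6) dir <- rnorm(3)
  tr <- unit3(dir) * runif(1, 0, max_translation)
  rigid_transform(rotation_about_axis(ax, ang), tr, from = from, to = to)
}
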