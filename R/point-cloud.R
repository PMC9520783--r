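# Point cloud container and region selection. Vertices are stored as a tibble
# (x, y, z in mm, optional r, g, b in 0..255); triangular faces, when present,
# are an M x 3 integer matrix of 0-based vertex indices (the PLY convention).

#' Point cloud
#'
#' Container for scans, scalp surfaces, and helmet meshes: vertices in
#' millimetres, optional per-vertex RGB colour in `[0, 255]`, optional
#' triangular faces (0-based vertex indices). Registration uses vertices only;
#' faces are carried through I/O but never interpreted.
#'
#' @param vertices N x 3 matrix or data frame with x/y/z columns (mm).
#' @param colors Optional N x 3 matrix or data frame (r/g/b columns) with
#'   values in `[0, 255]`.
#' @param faces Optional M x 3 matrix of 0-based vertex indices.
#' @return An object of class `point_cloud` with elements `vertices` (tibble
#'   of x, y, z and, when coloured, r, g, b) and `faces`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' n_vertices(pc)
#' @export
point_cloud <- function(vertices, colors = NULL, faces = NULL) {
  if (is.data.frame(vertices) && is.null(colors) &&
      all(c("r", "g", "b") %in% names(vertices))) {
    colors <- cbind(vertices$r, vertices$g, vertices$b)
  }
  v <- as_xyz(vertices, "vertices")
  if (nrow(v) < 1) abort_input("A point cloud needs at least one vertex.")
  vt <- xyz_tibble(v)
  if (!is.null(colors)) {
    if (is.data.frame(colors)) colors <- cbind(colors$r, colors$g, colors$b)
    colors <- as.matrix(colors)
    if (ncol(colors) != 3 || nrow(colors) != nrow(v)) {
      abort_input("`colors` must be N x 3, matching the vertex count.")
    }
    if (!all(is.finite(colors)) || min(colors) < 0 || max(colors) > 255) {
      abort_input("`colors` must lie in [0, 255].")
    }
    vt$r <- as.numeric(colors[, 1])
    vt$g <- as.numeric(colors[, 2])
    vt$b <- as.numeric(colors[, 3])
  }
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    if (ncol(faces) != 3) abort_input("`faces` must be an M x 3 index matrix.")
    storage.mode(faces) <- "integer"
    if (nrow(faces) > 0 && (min(faces) < 0 || max(faces) >= nrow(v))) {
      abort_input("Face indices must lie in [0, N) (0-based).")
    }
    dimnames(faces) <- NULL
    if (nrow(faces) == 0) faces <- NULL
  }
  structure(list(vertices = vt, faces = faces), class = "point_cloud")
}

#' @export
is_point_cloud <- function(x) inherits(x, "point_cloud")

#' Number of vertices in a point cloud
#' @param cloud A [point_cloud()].
#' @export
n_vertices <- function(cloud) {
  stopifnot(is_point_cloud(cloud))
  nrow(cloud$vertices)
}

has_colors <- function(cloud) all(c("r", "g", "b") %in% names(cloud$vertices))

cloud_xyz <- function(cloud) as_xyz(cloud$vertices, "vertices")

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d vertices%s%s\n", n_vertices(x),
              if (has_colors(x)) ", coloured" else "",
              if (!is.null(x$faces)) sprintf(", %d faces", nrow(x$faces)) else ""))
  invisible(x)
}

#' @export
as_tibble.point_cloud <- function(x, ...) x$vertices

#' @rdname tidy_opmcoreg
#' @export
tidy.point_cloud <- function(x, ...) x$vertices

#' Apply a rigid transform to a point cloud
#'
#' Transforms the vertices; colours and faces are carried along unchanged.
#'
#' @param cloud A [point_cloud()].
#' @param transform A [rigid_transform()].
#' @return A transformed [point_cloud()].
#' @export
transform_cloud <- function(cloud, transform) {
  stopifnot(is_point_cloud(cloud))
  v <- transform_points(cloud_xyz(cloud), transform)
  out <- cloud
  out$vertices$x <- v[, 1]
  out$vertices$y <- v[, 2]
  out$vertices$z <- v[, 3]
  out
}

#' Region selection within a point cloud
#'
#' A validated set of vertex indices (1-based) into a point cloud, the
#' scriptable stand-in for interactive face/helmet area picking.
#'
#' @param indices Unique vertex indices (1-based), non-empty.
#' @param description Free-text description, e.g. `"face area"`.
#' @return An object of class `region_selection`.
#' @export
region_selection <- function(indices, description = "") {
  indices <- as.integer(indices)
  if (length(indices) == 0) abort_input("A region selection cannot be empty.")
  if (anyNA(indices) || any(indices < 1)) {
    abort_input("Region indices must be positive integers.")
  }
  if (anyDuplicated(indices)) abort_input("Region indices must be unique.")
  structure(list(indices = indices, description = as.character(description)),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("<region_selection> %d vertices%s\n", length(x$indices),
              if (nzchar(x$description)) paste0(" (", x$description, ")") else ""))
  invisible(x)
}

#' Crop a point cloud to a selected region
#'
#' Keeps only the selected vertices; colours are carried along, faces are
#' dropped (cropping invalidates face indexing and registration only uses
#' vertices).
#'
#' @param cloud A [point_cloud()].
#' @param selection A [region_selection()].
#' @return A cropped [point_cloud()] without faces.
#' @export
crop_region <- function(cloud, selection) {
  stopifnot(is_point_cloud(cloud), inherits(selection, "region_selection"))
  if (max(selection$indices) > n_vertices(cloud)) {
    abort_input("Region selection indexes beyond the cloud's vertex count.")
  }
  structure(list(vertices = cloud$vertices[selection$indices, , drop = FALSE],
                 faces = NULL),
            class = "point_cloud")
}

#' Select vertices inside a sphere
#'
#' Scriptable replacement for GUI region picking: selects every vertex within
#' `radius` of `center` (closed ball).
#'
#' @param cloud A [point_cloud()].
#' @param center Length-3 sphere centre (mm).
#' @param radius Sphere radius (mm), `> 0`.
#' @param description Optional selection description.
#' @return A [region_selection()].
#' @export
select_by_sphere <- function(cloud, center, radius,
                             description = "sphere selection") {
  stopifnot(is_point_cloud(cloud))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort_input("`radius` must be a positive scalar (mm).")
  }
  center <- drop(as_xyz(center, "center"))
  v <- cloud_xyz(cloud)
  d2 <- (v[, 1] - center[1])^2 + (v[, 2] - center[2])^2 + (v[, 3] - center[3])^2
  idx <- which(d2 <= radius^2)
  if (length(idx) == 0) {
    abort_input("No vertices fall inside the selection sphere.")
  }
  region_selection(idx, description)
}
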