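# PLY mesh I/O. Supports the two dialects seen in practice from scanner and
# segmentation exports: ASCII and binary-little-endian. Vertex properties
# x/y/z (any float/int type) and optional red/green/blue are read; unknown
# properties are skipped with a warning; the face element, when present, must
# be triangular.

PLY_TYPE_SIZES <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_type_size <- function(type) {
  s <- PLY_TYPE_SIZES[[type]]
  if (is.null(s)) abort_format(sprintf("Unknown PLY property type '%s'.", type))
  s
}

ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")

read_ply_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) {
    abort_format("Not a PLY file (missing 'ply' magic line).")
  }
  format <- NULL
  elements <- list()
  current <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) abort_format("Truncated PLY header (no end_header).")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2], count = as.integer(tok[3]),
                      properties = list())
    } else if (tok[1] == "property") {
      if (is.null(current)) abort_format("PLY property outside an element.")
      if (tok[2] == "list") {
        prop <- list(name = tok[5], list = TRUE,
                     count_type = tok[3], index_type = tok[4])
      } else {
        prop <- list(name = tok[3], list = FALSE, type = tok[2])
      }
      current$properties[[prop$name]] <- prop
    } else if (tok[1] == "end_header") {
      if (!is.null(current)) elements[[current$name]] <- current
      break
    } else {
      abort_format(sprintf("Unrecognized PLY header line: '%s'.", line))
    }
  }
  if (is.null(format)) abort_format("PLY header lacks a format line.")
  if (!format %in% c("ascii", "binary_little_endian")) {
    abort_format(sprintf(
      "Unsupported PLY dialect '%s' (only ascii and binary_little_endian are supported).",
      format))
  }
  list(format = format, elements = elements)
}

#' Read a PLY mesh or point cloud
#'
#' Reads ASCII or binary-little-endian PLY files: vertex coordinates (any
#' numeric type), optional `red`/`green`/`blue` per-vertex colour, and an
#' optional triangular face element. Unknown vertex properties are ignored
#' with a warning; binary-big-endian files raise an unsupported-dialect error.
#'
#' @param path Path to a `.ply` file.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("PLY file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- read_ply_header(con)
  vx <- hdr$elements[["vertex"]]
  if (is.null(vx)) abort_format("PLY file has no vertex element.")
  vprops <- vx$properties
  if (!all(c("x", "y", "z") %in% names(vprops))) {
    abort_format("PLY vertex element lacks x/y/z properties.")
  }
  if (any(vapply(vprops, function(p) p$list, logical(1)))) {
    abort_format("List-typed vertex properties are not supported.")
  }
  known <- c("x", "y", "z", "red", "green", "blue")
  unknown <- setdiff(names(vprops), known)
  if (length(unknown) > 0) {
    warn(sprintf("Ignoring unknown PLY vertex properties: %s.",
                 paste(unknown, collapse = ", ")))
  }
  fc <- hdr$elements[["face"]]
  if (hdr$format == "ascii") {
    out <- read_ply_ascii(con, vx, fc)
  } else {
    out <- read_ply_binary(con, vx, fc)
  }
  cols <- NULL
  if (all(c("red", "green", "blue") %in% names(vprops))) {
    cols <- cbind(out$vertex[["red"]], out$vertex[["green"]], out$vertex[["blue"]])
  }
  verts <- cbind(out$vertex[["x"]], out$vertex[["y"]], out$vertex[["z"]])
  if (!all(is.finite(verts))) {
    abort_format("PLY vertices contain non-finite coordinates.")
  }
  point_cloud(verts, colors = cols, faces = out$faces)
}

read_ply_ascii <- function(con, vx, fc) {
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < vx$count) abort_format("Truncated PLY body (vertices).")
  vl <- strsplit(trimws(lines[seq_len(vx$count)]), "\\s+")
  np <- length(vx$properties)
  if (any(lengths(vl) < np)) abort_format("Malformed PLY vertex line.")
  vm <- matrix(as.numeric(unlist(lapply(vl, `[`, seq_len(np)))),
               ncol = np, byrow = TRUE)
  vertex <- setNames(lapply(seq_len(np), function(j) vm[, j]),
                     names(vx$properties))
  faces <- NULL
  if (!is.null(fc) && fc$count > 0) {
    fl <- lines[vx$count + seq_len(fc$count)]
    if (length(fl) < fc$count || anyNA(fl)) {
      abort_format("Truncated PLY body (faces).")
    }
    ft <- strsplit(trimws(fl), "\\s+")
    counts <- vapply(ft, function(x) as.integer(x[1]), integer(1))
    if (any(counts != 3L)) {
      abort_format("Only triangular PLY faces are supported.")
    }
    faces <- matrix(as.integer(unlist(lapply(ft, `[`, 2:4))),
                    ncol = 3, byrow = TRUE)
  }
  list(vertex = vertex, faces = faces)
}

read_ply_binary <- function(con, vx, fc) {
  types <- vapply(vx$properties, function(p) p$type, character(1))
  sizes <- vapply(types, ply_type_size, integer(1))
  rec <- sum(sizes)
  raw <- readBin(con, "raw", n = rec * vx$count)
  if (length(raw) < rec * vx$count) abort_format("Truncated PLY body (vertices).")
  bytes <- matrix(raw, nrow = rec)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  vertex <- vector("list", length(types))
  names(vertex) <- names(vx$properties)
  for (j in seq_along(types)) {
    sub <- as.vector(bytes[offs[j] + seq_len(sizes[j]), , drop = FALSE])
    what <- if (ply_is_float(types[j])) "double" else "integer"
    signed <- !types[j] %in% c("uchar", "uint8", "ushort", "uint16")
    sz <- sizes[j]
    if (what == "double" && sz == 4) {
      vertex[[j]] <- readBin(sub, "numeric", n = vx$count, size = 4,
                             endian = "little")
    } else if (what == "double") {
      vertex[[j]] <- readBin(sub, "numeric", n = vx$count, size = 8,
                             endian = "little")
    } else {
      vertex[[j]] <- readBin(sub, "integer", n = vx$count, size = sz,
                             signed = if (sz == 4) TRUE else signed,
                             endian = "little")
    }
  }
  faces <- NULL
  if (!is.null(fc) && fc$count > 0) {
    lp <- fc$properties[[1]]
    if (!lp$list) abort_format("PLY face element must be a list property.")
    cs <- ply_type_size(lp$count_type)
    is <- ply_type_size(lp$index_type)
    frec <- cs + 3L * is
    raw <- readBin(con, "raw", n = frec * fc$count)
    if (length(raw) < frec * fc$count) abort_format("Truncated PLY body (faces).")
    fb <- matrix(raw, nrow = frec)
    counts <- readBin(as.vector(fb[seq_len(cs), , drop = FALSE]), "integer",
                      n = fc$count, size = cs, signed = cs == 4,
                      endian = "little")
    if (any(counts != 3L)) {
      abort_format("Only triangular PLY faces are supported.")
    }
    faces <- matrix(NA_integer_, nrow = fc$count, ncol = 3)
    for (k in 1:3) {
      sub <- as.vector(fb[cs + (k - 1L) * is + seq_len(is), , drop = FALSE])
      faces[, k] <- readBin(sub, "integer", n = fc$count, size = is,
                            signed = is == 4, endian = "little")
    }
  }
  list(vertex = vertex, faces = faces)
}

#' Write a point cloud or mesh to PLY
#'
#' Writes coordinates as `double` (lossless round-trip through [read_ply()]),
#' colours as `uchar`, and faces as a triangular list element. Colour and face
#' elements are only emitted when present in the cloud.
#'
#' @param cloud A [point_cloud()].
#' @param path Output path.
#' @param binary If `TRUE`, writes binary-little-endian; otherwise ASCII.
#' @return The path, invisibly.
#' @export
write_ply <- function(cloud, path, binary = FALSE) {
  stopifnot(is_point_cloud(cloud))
  n <- n_vertices(cloud)
  colored <- has_colors(cloud)
  nf <- if (is.null(cloud$faces)) 0L else nrow(cloud$faces)
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    if (colored) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    if (nf > 0) c(sprintf("element face %d", nf),
                  "property list uchar int vertex_indices"),
    "end_header")
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing: %s", path, conditionMessage(e)),
          class = c("opmcoreg_error_io", "opmcoreg_error"))
  })
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  v <- cloud_xyz(cloud)
  if (binary) {
    if (colored) {
      cols <- round(cbind(cloud$vertices$r, cloud$vertices$g,
                          cloud$vertices$b))
      storage.mode(cols) <- "integer"
      for (i in seq_len(n)) {
        writeBin(v[i, ], con, size = 8, endian = "little")
        writeBin(as.raw(cols[i, ]), con)
      }
    } else {
      writeBin(as.vector(t(v)), con, size = 8, endian = "little")
    }
    if (nf > 0) {
      for (i in seq_len(nf)) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(cloud$faces[i, ]), con, size = 4, endian = "little")
      }
    }
  } else {
    if (colored) {
      body <- sprintf("%.17g %.17g %.17g %d %d %d", v[, 1], v[, 2], v[, 3],
                      as.integer(round(cloud$vertices$r)),
                      as.integer(round(cloud$vertices$g)),
                      as.integer(round(cloud$vertices$b)))
    } else {
      body <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
    }
    writeLines(body, con)
    if (nf > 0) {
      writeLines(sprintf("3 %d %d %d", cloud$faces[, 1], cloud$faces[, 2],
                         cloud$faces[, 3]), con)
    }
  }
  invisible(path)
}
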