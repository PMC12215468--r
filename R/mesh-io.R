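# Mesh file I/O: binary little-endian PLY with optional per-vertex scalar
# ("signed_distance") and uchar RGB channels, and binary STL (geometry only).

#' Write a mesh as binary PLY
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param scalar optional per-vertex scalar written as float property
#'   `signed_distance`; defaults to the mesh's scalar channel if present.
#' @param rgb optional n x 3 integer matrix (0-255) written as uchar
#'   red/green/blue.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalar = mesh$scalar, rgb = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    if (length(scalar) != nv) stop("scalar must have one value per vertex")
    props <- c(props, "property float signed_distance")
  }
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (nrow(rgb) != nv || ncol(rgb) != 3L) stop("rgb must be n x 3")
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
  }
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment bonequiv mesh",
           paste("element vertex", nv), props,
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  fl <- mesh$vertices
  if (!is.null(scalar)) fl <- cbind(fl, as.numeric(scalar))
  flraw <- writeBin(as.numeric(t(fl)), raw(), size = 4L, endian = "little")
  flm <- matrix(flraw, nrow = 4L * ncol(fl))
  if (!is.null(rgb)) {
    vm <- rbind(flm, matrix(as.raw(t(rgb)), nrow = 3L))
  } else vm <- flm
  firaw <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4L,
                    endian = "little")
  fim <- rbind(matrix(as.raw(3L), nrow = 1L, ncol = nf),
               matrix(firaw, nrow = 12L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.vector(vm), con)
  writeBin(as.vector(fim), con)
  invisible(path)
}

#' Read a binary little-endian PLY mesh
#'
#' Supports float/uchar vertex properties and triangular faces, i.e. the
#' subset written by [write_ply()] (and common mesh tools). A
#' `signed_distance` property is restored as the mesh scalar channel.
#'
#' @param path PLY file path.
#' @return a [triangle_mesh]; RGB channels, if present, are attached as
#'   attribute `rgb`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL
  nv <- nf <- 0L
  vprops <- character(0)
  vtypes <- character(0)
  element <- ""
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      element <- tok[2]
      if (element == "vertex") nv <- as.integer(tok[3])
      if (element == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && element == "vertex") {
      if (tok[2] == "list") stop("list properties on vertices are unsupported")
      vtypes <- c(vtypes, tok[2])
      vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (!identical(fmt, "binary_little_endian"))
    stop("only binary little-endian PLY is supported")
  sizes <- c(float = 4L, float32 = 4L, double = 8L, uchar = 1L, uint8 = 1L,
             char = 1L, int = 4L, int32 = 4L, uint = 4L)
  vs <- sizes[vtypes]
  if (any(is.na(vs))) stop("unsupported vertex property type")
  stride <- sum(vs)
  vraw <- matrix(readBin(con, "raw", n = stride * nv), nrow = stride)
  offs <- cumsum(c(0L, vs))
  getprop <- function(i) {
    sel <- vraw[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]
    what <- if (vs[i] >= 4L && vtypes[i] %in% c("float", "float32", "double"))
      "double" else "integer"
    readBin(as.vector(sel), what, n = nv, size = vs[i], endian = "little",
            signed = vs[i] > 1L)
  }
  vals <- lapply(seq_along(vprops), getprop)
  names(vals) <- vprops
  V <- cbind(vals$x, vals$y, vals$z)
  faces <- matrix(0L, nf, 3L)
  for (f in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1L))
    idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
    if (cnt != 3L) stop("only triangular faces are supported")
    faces[f, ] <- idx + 1L
  }
  mesh <- triangle_mesh(V, faces, scalar = vals$signed_distance)
  if (all(c("red", "green", "blue") %in% vprops))
    attr(mesh, "rgb") <- cbind(vals$red, vals$green, vals$blue)
  mesh
}

#' Write a mesh as binary STL (geometry only)
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  V <- mesh$vertices
  Fc <- mesh$faces
  nf <- nrow(Fc)
  v0 <- V[Fc[, 1], , drop = FALSE]
  v1 <- V[Fc[, 2], , drop = FALSE]
  v2 <- V[Fc[, 3], , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- pmax(sqrt(rowSums(n^2)), 1e-300)
  n <- n / len
  block <- t(cbind(n, v0, v1, v2)) # 12 floats per facet
  flraw <- matrix(writeBin(as.numeric(block), raw(), size = 4L,
                           endian = "little"), nrow = 48L)
  out <- rbind(flraw, matrix(as.raw(0L), nrow = 2L, ncol = nf))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  writeBin(as.vector(out), con)
  invisible(path)
}
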