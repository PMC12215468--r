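# Binary segmentation volumes with physical geometry. Mesh coordinates follow
# the convention mm = origin + index * spacing with zero-based (x, y, z) =
# (column, row, slice) indices, i.e. the first array dimension is x.

#' Binary segmentation volume with physical voxel geometry
#'
#' @param mask 3D array of 0/1 (logical or numeric).
#' @param spacing voxel spacing in mm, length 3 (x, y, z); z is the slice
#'   thickness.
#' @param origin physical position (mm) of the centre of voxel (0, 0, 0).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  m <- array(as.integer(mask != 0), dim = dim(mask))
  structure(list(mask = m, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$mask), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, ", sum(x$mask), " foreground\n", sep = "")
  invisible(x)
}

#' Occupied volume of a binary grid
#'
#' @param grid a [voxel_grid].
#' @return foreground voxel count times voxel volume, in mm^3.
#' @export
grid_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  sum(grid$mask) * prod(grid$spacing)
}

#' Read and write binary masks as NIfTI
#'
#' Masks are stored as unsigned 8-bit volumes with the voxel spacing in the
#' header and the origin in the qform offset.
#'
#' @param grid a [voxel_grid].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti_mask` returns `path` invisibly; `read_nifti_mask`
#'   returns a [voxel_grid].
#' @export
write_nifti_mask <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- grid$mask
  attr(arr, "pixdim") <- grid$spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  xf <- diag(4)
  diag(xf)[1:3] <- grid$spacing
  xf[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_mask
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  # the RAS xform may carry sign flips; recover the stored origin from the
  # axis-aligned case (the only case this package writes)
  ax <- abs(xf[1:3, 1:3])
  if (max(abs(ax - diag(spacing))) > 1e-4 * max(spacing))
    warning("non axis-aligned orientation; origin taken from the xform offset")
  neg <- diag(xf[1:3, 1:3]) < 0
  if (any(neg)) {
    d <- dim(img)
    for (a in which(neg)) origin[a] <- xf[a, a] * (d[a] - 1) + origin[a]
  }
  voxel_grid(array(as.integer(img > 0.5), dim = dim(img)), spacing, origin)
}

#' Read and write binary masks as MetaImage (.mha)
#'
#' Single-file MetaImage with `MET_UCHAR` data, mm units, spacing and origin
#' in the header.
#'
#' @param grid a [voxel_grid].
#' @param path file path ending in `.mha`.
#' @return `write_mha_mask` returns `path` invisibly; `read_mha_mask` a
#'   [voxel_grid].
#' @export
write_mha_mask <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$mask)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_UCHAR",
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.raw(grid$mask), con)
  invisible(path)
}

#' @rdname write_mha_mask
#' @export
read_mha_mask <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementType"]], "MET_UCHAR"))
    stop("only MET_UCHAR MetaImage volumes are supported")
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage volumes are supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  raw <- readBin(con, "raw", n = prod(d))
  voxel_grid(array(as.integer(raw), dim = d), spacing, origin)
}
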