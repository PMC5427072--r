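#' Masked 4-D time-series volume
#'
#' In-memory container for a BOLD-like 4-D image: a numeric array `(x, y, z,
#' t)`, an in-brain mask, a voxel-to-world affine and the sampling interval.
#' Voxels outside the mask are held at exactly zero.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param mask 3-D logical array matching the spatial dimensions.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param voxel_mm Isotropic voxel edge length in mm (used to build the default
#'   affine).
#' @param affine Optional 4x4 voxel-to-world transform; defaults to an
#'   MNI-like toy transform with the origin at the grid centre.
#' @return A `volume_series` object.
#' @export
volume_series <- function(data, mask, tr_s = 2, voxel_mm = 2, affine = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  dims <- dim(data)
  if (dims[4] < 2L) stop("need at least 2 time points")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  mask <- array(as.logical(mask), dims[1:3])
  if (!identical(dim(mask), dims[1:3])) stop("mask shape must match data")
  if (is.null(affine)) affine <- default_affine(dims[1:3], voxel_mm)
  stopifnot(is.matrix(affine), identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(list(data = data, mask = mask, affine = affine, tr_s = tr_s,
                 voxel_mm = voxel_mm),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d voxels x %d time points, TR %g s, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' 3-D scalar brain map
#'
#' Container for a per-voxel scalar map (regional homogeneity, fALFF, a
#' correlation map, or a conjunction map) on the same grid as its source
#' volume. Values are finite exactly on the defined part of the mask;
#' everywhere else they are `NA`.
#'
#' @param values 3-D numeric array.
#' @param mask 3-D logical array.
#' @param affine 4x4 voxel-to-world transform.
#' @param kind One of `"reho"`, `"falff"`, `"r"`, `"conjunction_r"`.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return A `brain_map` object.
#' @export
brain_map <- function(values, mask, affine = NULL, kind = "r", voxel_mm = 2) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  kind <- match.arg(kind, c("reho", "falff", "r", "conjunction_r"))
  mask <- array(as.logical(mask), dim(values))
  if (is.null(affine)) affine <- default_affine(dim(values), voxel_mm)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, affine = affine, kind = kind,
                 voxel_mm = voxel_mm),
            class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$mask]
  cat(sprintf("<brain_map:%s> %dx%dx%d, %d in mask (%d undefined), range [%.3g, %.3g]\n",
              x$kind, d[1], d[2], d[3], sum(x$mask), sum(is.na(v)),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

# MNI-like toy affine: RAS axes, isotropic voxels, origin at the grid centre
default_affine <- function(dims, voxel_mm) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- -voxel_mm * (dims - 1) / 2
  a
}

#' Convert voxel indices to world coordinates
#'
#' @param ijk Matrix (n x 3) of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world transform (0-based voxel convention).
#' @return Matrix (n x 3) of world-space mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Write a volume or map to a NIfTI-1 file
#'
#' The repetition time (for 4-D series) and voxel size are carried in the
#' header pixdim. Undefined map voxels are written as NaN.
#'
#' @param x A `volume_series` or `brain_map`.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, file) {
  if (inherits(x, "volume_series")) {
    arr <- x$data
    pd <- c(rep(x$voxel_mm, 3), x$tr_s)
  } else if (inherits(x, "brain_map")) {
    arr <- x$values
    arr[is.na(arr)] <- NaN
    pd <- rep(x$voxel_mm, 3)
  } else if (is.array(x)) {
    arr <- x
    pd <- rep(2, min(length(dim(x)), 3))
  } else stop("cannot write object of class ", class(x)[1])
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a 4-D NIfTI file as a volume_series
#'
#' @param file Path to a 4-D NIfTI image.
#' @param mask Optional 3-D logical array or path to a mask NIfTI; defaults to
#'   voxels with nonzero temporal variance.
#' @return A `volume_series`.
#' @export
read_volume_series <- function(file, mask = NULL) {
  img <- RNifti::readNifti(file)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L) stop("expected a 4-D image")
  pd <- RNifti::pixdim(img)
  if (is.character(mask)) {
    m <- RNifti::readNifti(mask)
    mask <- array(as.numeric(m) != 0, dim(arr)[1:3])
  }
  if (is.null(mask)) {
    v <- apply(arr, 1:3, stats::var)
    mask <- v > 0
  }
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  volume_series(arr, mask, tr_s = tr, voxel_mm = pd[1])
}

#' Read a 3-D NIfTI file as a brain_map
#'
#' @param file Path to a 3-D NIfTI image.
#' @param mask 3-D logical array or path to a mask NIfTI; defaults to finite
#'   nonzero voxels.
#' @param kind Map kind.
#' @return A `brain_map`.
#' @export
read_brain_map <- function(file, mask = NULL, kind = "r") {
  img <- RNifti::readNifti(file)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3-D image")
  if (is.character(mask)) {
    m <- RNifti::readNifti(mask)
    mask <- array(as.numeric(m) != 0, dim(arr))
  }
  if (is.null(mask)) mask <- is.finite(arr) & arr != 0
  brain_map(arr, mask, kind = kind, voxel_mm = RNifti::pixdim(img)[1])
}
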