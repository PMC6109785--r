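#' 4D brain time-series volume
#'
#' A light container for one subject's X×Y×Z×T BOLD series: the data grid,
#' a voxel-to-world affine (RAS, mm), the repetition time, and a 3D brain
#' mask. All pipeline stages operate on this object or on its masked
#' time-by-voxel matrix view.
#'
#' @param data numeric 4D array (X, Y, Z, T).
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal RAS
#'   affine with the given `voxdim_mm`.
#' @param tr repetition time in seconds.
#' @param mask logical 3D array matching the spatial dims; defaults to all
#'   `TRUE`.
#' @param voxdim_mm voxel size in mm used when `affine` is `NULL`.
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, affine = NULL, tr = 2.5, mask = NULL,
                     voxdim_mm = c(3, 3, 3)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  d <- dim(data)
  if (d[4] < 2) stop("volume4d needs at least 2 timepoints")
  if (is.null(affine)) {
    affine <- diag(c(voxdim_mm, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  if (is.null(mask)) {
    mask <- array(TRUE, d[1:3])
  }
  stopifnot(all(dim(mask) == d[1:3]))
  if (!all(is.finite(data[rep(as.vector(mask), d[4])])))
    stop("non-finite values inside the brain mask")
  structure(list(data = data, affine = affine, tr = tr,
                 mask = array(as.logical(mask), d[1:3])),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d grid, %d timepoints, TR=%gs, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Masked matrix view of a 4D volume
#'
#' @param vol a `volume4d`.
#' @return a T × n_voxel matrix of in-mask time series (column order follows
#'   the array linearization of the mask).
#' @export
vol_matrix <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  t(m[as.vector(vol$mask), , drop = FALSE])
}

#' Rebuild a 4D volume from a masked time-by-voxel matrix
#'
#' @param mat T × n_voxel matrix.
#' @param like a `volume4d` providing grid, affine, TR and mask.
#' @return a `volume4d` with out-of-mask voxels set to 0.
#' @export
matrix_to_vol <- function(mat, like) {
  d <- dim(like$data)
  full <- matrix(0, prod(d[1:3]), d[4])
  full[as.vector(like$mask), ] <- t(mat)
  volume4d(array(full, d), affine = like$affine, tr = like$tr,
           mask = like$mask)
}

#' Embed a masked voxel vector into a 3D array
#' @param v numeric vector, one value per in-mask voxel.
#' @param mask logical 3D array.
#' @param fill value used outside the mask.
#' @return 3D array of `dim(mask)`.
#' @export
unmask <- function(v, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- v
  out
}

#' Write a volume to a NIfTI-1 file
#'
#' The TR is recorded in the time-dimension pixdim.
#'
#' @param vol a `volume4d`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, c(abs(diag(vol$affine)[1:3]), vol$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI-1 file into a `volume4d`
#'
#' @param path NIfTI file.
#' @param mask optional logical 3D array; defaults to voxels with nonzero
#'   temporal variance.
#' @return a `volume4d`.
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4) pd[4] else 1
  if (is.null(mask)) {
    d <- dim(arr)
    v <- matrixStats_colVars(matrix(arr, prod(d[1:3]), d[4]))
    mask <- array(v > 0, d[1:3])
  }
  volume4d(arr, tr = tr, mask = mask)
}

# row-variance helper without extra deps
matrixStats_colVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}
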