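#' Discrete-cosine high-pass projection
#'
#' Removes slow signal drift by projecting out a discrete cosine basis: all
#' DCT components with period longer than `cutoff_s`, plus the constant. The
#' operation is an orthogonal projection, hence idempotent, and is applied
#' identically to data and regressors by the GLM so that drift removal does
#' not bias the condition estimates.
#'
#' Component `k` of the DCT basis over `n` scans has period `2 n tr_s / k`;
#' components with `k <= floor(2 n tr_s / cutoff_s)` are removed.
#'
#' @param x Numeric matrix, one time course per column (a vector is treated
#'   as a single column), scans in rows.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @return Matrix of the same shape with the low-frequency span removed.
#' @export
dct_highpass_project <- function(x, tr_s, cutoff_s = 128) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 time points")
  if (cutoff_s <= 2 * tr_s) {
    stop("cutoff_s must exceed twice the sampling interval")
  }
  B <- dct_basis(n, tr_s, cutoff_s)
  x - B %*% crossprod(B, x)
}

# Orthonormal DCT-II drift basis: constant plus components with period > cutoff
dct_basis <- function(n, tr_s, cutoff_s) {
  k_max <- floor(2 * n * tr_s / cutoff_s)
  t <- seq_len(n) - 1
  B <- matrix(1 / sqrt(n), n, 1)
  if (k_max >= 1) {
    Bk <- vapply(seq_len(k_max),
                 function(k) sqrt(2 / n) * cos(pi * k * (2 * t + 1) / (2 * n)),
                 numeric(n))
    B <- cbind(B, Bk)
  }
  B
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Convolves a volume with an anisotropic Gaussian specified by its full width
#' at half maximum in mm per axis; the kernel standard deviation in voxel
#' units is `(fwhm / voxel_size) / sqrt(8 log 2)`. Boundaries are handled by
#' reflection, which preserves the volume mean exactly for the symmetric,
#' unit-mass kernel used. `fwhm_mm = 0` (any axis) leaves that axis untouched.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm FWHM in mm; scalar (isotropic) or triple.
#' @param voxel_size_mm Voxel edge lengths in mm, triple.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(volume)) == 3)
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  stopifnot(length(fwhm_mm) == 3, length(voxel_size_mm) == 3)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be nonnegative")
  out <- volume
  for (ax in 1:3) {
    out <- smooth_along_axis(out, ax, fwhm_mm[ax] / voxel_size_mm[ax])
  }
  out
}

# Smooth a 3-D (or trailing-dim-augmented) array along one axis; fwhm_vox in
# voxel units. Implemented as multiplication with a reflective-boundary
# convolution matrix so whole volumes (or 4-D stacks) go through one GEMM.
smooth_along_axis <- function(arr, axis, fwhm_vox) {
  if (fwhm_vox == 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  K <- gauss_conv_matrix(n, fwhm_vox / sqrt(8 * log(2)))
  perm <- c(axis, seq_along(d)[-axis])
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

# n x n convolution matrix for a normalized Gaussian, reflective boundary
gauss_conv_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    # reflect around the edges (half-sample symmetric)
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    # repeated reflection for kernels wider than the axis
    while (any(idx < 1 | idx > n)) {
      idx <- ifelse(idx < 1, 1 - idx, idx)
      idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    }
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + k[j]
  }
  K
}

#' Smooth every volume of a 4-D run
#'
#' @param run 4-D array (x, y, z, time).
#' @inheritParams gaussian_smooth
#' @return 4-D array of the same dimensions.
#' @export
smooth_run <- function(run, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(run)) == 4)
  if (length(fwhm_mm) == 1) fwhm_mm <- rep(fwhm_mm, 3)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be nonnegative")
  out <- run
  for (ax in 1:3) {
    out <- smooth_along_axis(out, ax, fwhm_mm[ax] / voxel_size_mm[ax])
  }
  out
}
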