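#' Fit the block-design GLM and extract per-run condition betas
#'
#' Voxelwise ordinary least squares. The discrete-cosine high-pass projection
#' ([dct_highpass_project()]) is applied, per run, to both the data and the
#' condition regressors before fitting; run-mean columns lie inside the
#' removed span (the projection removes the constant), so each run reduces to
#' an OLS fit of its filtered condition regressors. This yields one beta map
#' per (stimulus category, run) — with the default design, 8 estimates per
#' category, relative to the fixation baseline.
#'
#' @param runs List of 4-D arrays (x, y, z, time), one per run.
#' @param X A [build_design_matrix()] design matrix.
#' @param mask 3-D logical array selecting brain voxels.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return A `beta_images` object: `data` (4-D array, one 3-D map per
#'   regressor of interest, `NA` outside the mask), `condition` and `run`
#'   labels per map, `mask`, and `grid_dims`.
#' @export
fit_glm <- function(runs, X, mask, cutoff_s = 128) {
  stopifnot(length(runs) == X$n_runs)
  if (!any(mask)) stop("mask is empty")
  dims <- dim(mask)
  n_scan <- X$n_scans_per_run
  cond_idx <- which(!is.na(X$condition))
  cats <- X$condition_names
  n_cat <- length(cats)
  vox <- which(mask)
  n_maps <- n_cat * X$n_runs
  beta <- matrix(NA_real_, length(vox), n_maps)
  map_cond <- character(n_maps); map_run <- integer(n_maps)
  for (r in seq_len(X$n_runs)) {
    arr <- runs[[r]]
    if (!all(dim(arr)[1:3] == dims) || dim(arr)[4] != n_scan) {
      stop(sprintf("run %d dimensions do not match mask/design", r))
    }
    Y <- t(matrix(arr, prod(dims), n_scan)[vox, , drop = FALSE])
    rows <- (r - 1) * n_scan + seq_len(n_scan)
    jr <- cond_idx[X$run[cond_idx] == r]
    Xr <- X$values[rows, jr, drop = FALSE]
    Xf <- dct_highpass_project(Xr, X$tr_s, cutoff_s)
    qrX <- qr(Xf)
    if (qrX$rank < ncol(Xf)) {
      bad <- paste(X$condition[jr[qrX$pivot[-seq_len(qrX$rank)]]], collapse = ", ")
      stop(sprintf("rank-deficient design in run %d (columns: %s)", r, bad))
    }
    Yf <- dct_highpass_project(Y, X$tr_s, cutoff_s)
    b <- qr.coef(qrX, Yf)
    for (k in seq_along(jr)) {
      m <- (r - 1) * n_cat + k
      beta[, m] <- b[k, ]
      map_cond[m] <- X$condition[jr[k]]
      map_run[m] <- r
    }
  }
  data <- array(NA_real_, c(dims, n_maps))
  flat <- matrix(data, prod(dims), n_maps)
  flat[vox, ] <- beta
  structure(list(data = array(flat, c(dims, n_maps)),
                 condition = map_cond, run = map_run,
                 mask = mask, grid_dims = dims),
            class = "beta_images")
}

#' Pull the 3-D beta map of one (category, run)
#' @param betas A `beta_images` object.
#' @param condition Category name.
#' @param run Run index.
#' @return 3-D array.
#' @export
beta_map <- function(betas, condition, run) {
  m <- which(betas$condition == condition & betas$run == run)
  if (length(m) != 1) stop("no unique map for that (condition, run)")
  array(betas$data[, , , m], betas$grid_dims)
}

#' Linear contrast of run-averaged betas
#'
#' Voxelwise `sum_c w_c * mean_over_runs(beta[c, run])`; with weights
#' `c(face = 1, object = -1)` this is the face-minus-object contrast used as
#' the univariate reference image.
#'
#' @param betas A `beta_images` object from [fit_glm()].
#' @param weights Named numeric vector covering every stimulus category in
#'   `betas` (zeros allowed and required to be explicit).
#' @return 3-D array, `NA` outside the mask.
#' @export
compute_contrast <- function(betas, weights) {
  cats <- unique(betas$condition)
  missing <- setdiff(cats, names(weights))
  if (length(missing)) {
    stop("weights missing for categories: ", paste(missing, collapse = ", "))
  }
  w <- weights[cats]
  dims <- betas$grid_dims
  out <- array(0, dims)
  for (cat in cats) {
    if (w[[cat]] == 0) next
    ms <- which(betas$condition == cat)
    out <- out + w[[cat]] * apply(betas$data[, , , ms, drop = FALSE], 1:3, mean)
  }
  out[!betas$mask] <- NA_real_
  out
}

#' Smooth, filter and fit one subject
#'
#' Convenience wrapper over the full single-subject estimation path: Gaussian
#' smoothing of every run (default one 4-mm pass; `smooth_passes = 2`
#' reproduces a smooth-at-preprocessing-plus-smooth-again reading, an
#' effective FWHM of about 5.7 mm), then [fit_glm()].
#'
#' @param runs List of 4-D arrays.
#' @param design The experiment design the runs follow.
#' @param mask 3-D logical brain mask.
#' @param fwhm_mm Smoothing FWHM in mm (scalar or triple); 0 disables.
#' @param smooth_passes Number of smoothing passes (1 or 2).
#' @param cutoff_s High-pass cutoff, seconds.
#' @param hrf HRF parameters.
#' @return A `beta_images` object.
#' @export
fit_subject_glm <- function(runs, design, mask, fwhm_mm = 4,
                            smooth_passes = 1L, cutoff_s = 128,
                            hrf = hrf_params()) {
  vs <- design$geometry$voxel_size_mm
  if (any(fwhm_mm > 0) && smooth_passes > 0) {
    for (p in seq_len(smooth_passes)) {
      runs <- lapply(runs, smooth_run, fwhm_mm = fwhm_mm, voxel_size_mm = vs)
    }
  }
  X <- build_design_matrix(design, hrf)
  fit_glm(runs, X, mask, cutoff_s)
}
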