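#' Single-subject univariate contrast test
#'
#' Voxelwise one-sample t across the per-run (first minus second category)
#' betas, with familywise correction over voxels by a sign-flip permutation
#' of the runs (all `2^n_runs` sign patterns when `n_runs <= 12`, so the null
#' is exact for the default 8 runs); when fewer than 6 runs are available the
#' max-statistic null is too coarse and a Bonferroni threshold is used
#' instead. A region is scored "present" if at least one supra-threshold
#' voxel falls inside its mask.
#'
#' @param betas A `beta_images` object.
#' @param pair Category pair, e.g. `c("face", "object")` (first minus
#'   second).
#' @param region_masks Named list of 3-D logical masks to score.
#' @param alpha_fwe Familywise level.
#' @return List: `stat_map`, `threshold`, `method`, and `region_presence`
#'   (data.frame: `region`, `present`, `peak_stat`, `n_supra`).
#' @export
single_subject_contrast_test <- function(betas, pair, region_masks,
                                         alpha_fwe = 0.05) {
  if (is.null(region_masks) || !length(region_masks)) {
    stop("region_masks are required")
  }
  stopifnot(length(pair) == 2)
  runs <- sort(unique(betas$run))
  n_runs <- length(runs)
  if (n_runs < 2) stop("need at least 2 runs")
  dims <- betas$grid_dims
  vox <- which(betas$mask)
  flat <- matrix(betas$data, prod(dims), length(betas$condition))
  C <- vapply(runs, function(r) {
    i1 <- which(betas$condition == pair[1] & betas$run == r)
    i2 <- which(betas$condition == pair[2] & betas$run == r)
    flat[vox, i1] - flat[vox, i2]
  }, numeric(length(vox)))                      # n_vox x n_runs
  t_of <- function(M) {
    mu <- rowMeans(M)
    s <- sqrt(rowSums((M - mu)^2) / (n_runs - 1))
    out <- mu / (s / sqrt(n_runs))
    out[s == 0] <- NA_real_
    out
  }
  t_obs <- t_of(C)
  if (n_runs >= 6 && n_runs <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_runs)))
    max_t <- apply(signs, 1, function(s) {
      v <- t_of(sweep(C, 2, s, `*`))
      v <- v[is.finite(v)]
      if (length(v)) max(v) else -Inf
    })
    threshold <- as.numeric(quantile(max_t, 1 - alpha_fwe, names = FALSE,
                                     type = 1))
    method <- "sign_flip_exact"
  } else {
    threshold <- critical_t(alpha_fwe / length(vox), n_runs - 1)
    method <- "bonferroni"
  }
  tmap <- array(NA_real_, dims)
  tmap[vox] <- t_obs
  presence <- do.call(rbind, lapply(names(region_masks), function(nm) {
    m <- region_masks[[nm]] & betas$mask
    v <- tmap[m]
    v <- v[is.finite(v)]
    data.frame(region = nm,
               present = any(v > threshold),
               peak_stat = if (length(v)) max(v) else NA_real_,
               n_supra = sum(v > threshold))
  }))
  list(stat_map = structure(list(data = tmap, df = n_runs - 1,
                                 test = "one_sample_vs_null"),
                            class = "stat_map"),
       threshold = threshold, method = method, alpha_fwe = alpha_fwe,
       region_presence = presence)
}

#' Group-level univariate contrast comparison
#'
#' Two-sample comparison (group A minus group B) of subject contrast images
#' with Welch's unequal-variance t by default, followed by permutation
#' cluster-level correction.
#'
#' @param contrasts_a,contrasts_b Lists of subject 3-D contrast maps.
#' @param equal_variance `FALSE` (Welch) by default.
#' @param ... Passed to [permutation_correct()].
#' @return The [permutation_correct()] result.
#' @export
group_univariate_contrast <- function(contrasts_a, contrasts_b,
                                      equal_variance = FALSE, ...) {
  permutation_correct(maps_a = contrasts_a, maps_b = contrasts_b,
                      scheme = "label_shuffle",
                      equal_variance = equal_variance, ...)
}
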