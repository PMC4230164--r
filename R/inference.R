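#' Voxelwise one-sample t map
#'
#' `t = (mean - null_value) / (sd / sqrt(n))` per voxel across subject maps,
#' df = n - 1. Used to compare group accuracy maps to the 50% chance level.
#' Zero-variance voxels are set `NA` and counted (attribute
#' `n_zero_variance`), not turned into infinities.
#'
#' @param maps List of subject 3-D maps, or a subjects x voxels matrix.
#' @param null_value The value under the null (0.5 for two-class decoding
#'   accuracy, 0 for contrasts).
#' @return A `stat_map`: `data` (3-D array or vector of t values), `df`,
#'   `test`, plus zero-variance bookkeeping.
#' @export
one_sample_t_map <- function(maps, null_value = 0) {
  M <- stack_maps(maps)
  n <- nrow(M$mat)
  if (n < 2) stop("need at least 2 subjects")
  mu <- colMeans(M$mat)
  s <- sqrt(colSums(sweep(M$mat, 2, mu)^2) / (n - 1))
  t <- (mu - null_value) / (s / sqrt(n))
  zero <- is.finite(mu) & s == 0
  t[zero] <- NA_real_
  new_stat_map(t, M, df = n - 1, test = "one_sample_vs_null",
               n_zero_variance = sum(zero))
}

#' Voxelwise two-sample t map (group A minus group B)
#'
#' Pooled-variance Student t (df = `n_a + n_b - 2`) or Welch t with
#' Welch-Satterthwaite df when `equal_variance = FALSE`.
#'
#' @param maps_a,maps_b Lists of subject 3-D maps (or matrices) per group.
#' @param equal_variance Pool the variances (default) or use the Welch form,
#'   as in the unequal-variance univariate group comparison.
#' @return A `stat_map`; for Welch, `df` is the map-median Welch df and a
#'   voxelwise `df_map` is attached.
#' @export
two_sample_t_map <- function(maps_a, maps_b, equal_variance = TRUE) {
  A <- stack_maps(maps_a); B <- stack_maps(maps_b)
  na <- nrow(A$mat); nb <- nrow(B$mat)
  if (na < 2 || nb < 2) stop("each group needs at least 2 subjects")
  ma <- colMeans(A$mat); mb <- colMeans(B$mat)
  va <- colSums(sweep(A$mat, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(B$mat, 2, mb)^2) / (nb - 1)
  if (equal_variance) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    df_map <- NULL
  } else {
    se <- sqrt(va / na + vb / nb)
    df_map <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    df <- stats::median(df_map[is.finite(df_map)])
  }
  t <- (ma - mb) / se
  zero <- is.finite(ma) & se == 0
  t[zero] <- NA_real_
  new_stat_map(t, A, df = df, test = "two_sample_diff",
               n_zero_variance = sum(zero), df_map = df_map)
}

stack_maps <- function(maps) {
  if (is.matrix(maps)) return(list(mat = maps, dims = NULL))
  dims <- dim(maps[[1]])
  mat <- matrix(unlist(lapply(maps, as.vector)), nrow = length(maps),
                byrow = TRUE)
  list(mat = mat, dims = dims)
}

new_stat_map <- function(t, stacked, df, test, n_zero_variance = 0,
                         df_map = NULL) {
  data <- if (is.null(stacked$dims)) t else array(t, stacked$dims)
  structure(list(data = data, df = df, test = test,
                 n_zero_variance = n_zero_variance,
                 df_map = if (!is.null(df_map) && !is.null(stacked$dims))
                   array(df_map, stacked$dims) else df_map),
            class = "stat_map")
}

#' Upper-tail critical t value
#'
#' `critical_t(0.001, 15)` returns 3.73 (to 2 decimals) — the display
#' threshold of the between-group map at df = 10 + 7 - 2.
#'
#' @param p Tail probability in (0, 1).
#' @param df Degrees of freedom.
#' @param tail `"one_sided_greater"` (default) or `"two_sided"` (the returned
#'   threshold is then the `p/2` upper quantile).
#' @return The t threshold.
#' @export
critical_t <- function(p, df, tail = c("one_sided_greater", "two_sided")) {
  tail <- match.arg(tail)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  qt(if (tail == "two_sided") p / 2 else p, df, lower.tail = FALSE)
}

#' Permutation familywise and cluster-level correction
#'
#' Builds the empirical null of the maximum voxel statistic (voxel-level FWE)
#' and of the maximum supra-threshold cluster extent (cluster-level FWE) by
#' sign-flipping subject maps around the null value (one-sample) or shuffling
#' group labels (two-sample). The identity permutation is always included, so
#' corrected p values are never below `1 / (1 + n_permutations)`.
#'
#' @param maps One-sample: list/matrix of subject maps. Two-sample: ignored,
#'   use `maps_a` / `maps_b`.
#' @param maps_a,maps_b Group maps for the two-sample scheme.
#' @param scheme `"sign_flip"` or `"label_shuffle"`.
#' @param null_value Null value subtracted before sign flipping.
#' @param n_permutations Number of random permutations (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param cluster_forming_p Voxelwise one-sided p defining the
#'   cluster-forming threshold `critical_t(cluster_forming_p, df)`.
#' @param alpha Familywise level for the reported voxel threshold.
#' @param connectivity Cluster connectivity: 6, 18 (default) or 26.
#' @param equal_variance Passed to [two_sample_t_map()] for the label-shuffle
#'   scheme.
#' @param geometry Optional [acq_geometry()] for mm peak coordinates.
#' @return List: `observed` (`stat_map`), `cluster_table` (see
#'   [extract_clusters()], plus `p_corrected`), `voxel_fwe_threshold`,
#'   `cluster_forming_t`, `max_stat_null`, `max_extent_null`.
#' @export
permutation_correct <- function(maps = NULL, maps_a = NULL, maps_b = NULL,
                                scheme = c("sign_flip", "label_shuffle"),
                                null_value = 0, n_permutations = 999L,
                                seed = 1L, cluster_forming_p = 0.001,
                                alpha = 0.05, connectivity = 18L,
                                equal_variance = TRUE, geometry = NULL) {
  scheme <- match.arg(scheme)
  if (n_permutations < 100) stop("use at least 100 permutations")
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1) {
    stop("cluster_forming_p must lie in (0, 1)")
  }
  if (scheme == "sign_flip") {
    if (is.null(maps)) stop("sign_flip needs `maps`")
    S <- stack_maps(maps)
    dims <- S$dims
    n <- nrow(S$mat)
    D <- S$mat - null_value
    t_fun <- function(signs) {
      M <- D * signs
      mu <- colMeans(M)
      s <- sqrt(colSums(sweep(M, 2, mu)^2) / (n - 1))
      out <- mu / (s / sqrt(n))
      out[s == 0] <- NA_real_
      out
    }
    df <- n - 1
    observed <- one_sample_shape_fix(one_sample_t_map(S$mat, null_value), dims)
    set.seed(seed)
    # identity first, then n_permutations random draws: corrected p is
    # (1 + #{random perm >= observed}) / (1 + n_permutations)
    perms <- c(list(rep(1, n)),
               lapply(seq_len(n_permutations),
                      function(i) sample(c(-1, 1), n, replace = TRUE)))
    perm_stat <- lapply(perms, t_fun)
  } else {
    if (is.null(maps_a) || is.null(maps_b)) {
      stop("label_shuffle needs `maps_a` and `maps_b`")
    }
    A <- stack_maps(maps_a); B <- stack_maps(maps_b)
    dims <- A$dims
    na <- nrow(A$mat)
    all_mat <- rbind(A$mat, B$mat)
    n_tot <- nrow(all_mat)
    t_fun <- function(ia) {
      sm <- two_sample_t_map(all_mat[ia, , drop = FALSE],
                             all_mat[-ia, , drop = FALSE],
                             equal_variance = equal_variance)
      as.vector(sm$data)
    }
    observed <- two_sample_t_map(A$mat, B$mat, equal_variance = equal_variance)
    df <- observed$df
    set.seed(seed)
    perms <- c(list(seq_len(na)),
               lapply(seq_len(n_permutations),
                      function(i) sample(n_tot, na)))
    perm_stat <- lapply(perms, t_fun)
    observed <- one_sample_shape_fix(observed, dims)
  }
  t_cf <- critical_t(cluster_forming_p, df)
  max_stat <- vapply(perm_stat, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) max(v) else -Inf
  }, numeric(1))
  if (is.null(dims)) stop("maps must be 3-D arrays for cluster inference")
  max_ext <- vapply(perm_stat, function(v) {
    max_cluster_extent(array(v, dims), t_cf, connectivity)
  }, numeric(1))
  obs_arr <- if (is.null(dim(observed$data))) array(observed$data, dims)
             else observed$data
  tab <- extract_clusters(
    structure(list(data = obs_arr, df = df, test = observed$test),
              class = "stat_map"),
    threshold = t_cf, connectivity = connectivity, geometry = geometry)
  if (nrow(tab)) {
    # the identity permutation is max_ext[1], providing the +1 in
    # (1 + #{perm >= observed}) / (1 + n_permutations)
    tab$p_corrected <- vapply(tab$extent, function(ke) {
      sum(max_ext >= ke) / length(max_ext)
    }, numeric(1))
  } else {
    tab$p_corrected <- numeric(0)
  }
  list(observed = observed,
       cluster_table = tab,
       voxel_fwe_threshold = as.numeric(quantile(max_stat, 1 - alpha,
                                                 names = FALSE, type = 1)),
       cluster_forming_t = t_cf,
       max_stat_null = max_stat,
       max_extent_null = max_ext,
       n_permutations = n_permutations, alpha = alpha, scheme = scheme)
}

one_sample_shape_fix <- function(sm, dims) {
  if (is.null(dim(sm$data)) && !is.null(dims)) sm$data <- array(sm$data, dims)
  sm
}
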