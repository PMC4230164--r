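#' Searchlight configuration
#'
#' @param radius_mm Sphere radius in mm (default 10, the roaming-searchlight
#'   radius used throughout the pipeline).
#' @param svm_cost Soft-margin cost C of the linear SVM.
#' @param min_sphere_voxels Centers whose sphere retains fewer in-mask voxels
#'   than this are left `NA`.
#' @param zscore Per-fold feature standardization (off by default; betas
#'   enter the classifier raw).
#' @return A list of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 10, svm_cost = 1,
                               min_sphere_voxels = 2L, zscore = FALSE) {
  stopifnot(radius_mm >= 0, svm_cost > 0, min_sphere_voxels >= 1)
  structure(list(radius_mm = radius_mm, svm_cost = svm_cost,
                 min_sphere_voxels = as.integer(min_sphere_voxels),
                 zscore = isTRUE(zscore)),
            class = "searchlight_config")
}

#' Integer voxel offsets of a sphere on an anisotropic grid
#'
#' All integer offsets `(i, j, k)` whose physical displacement
#' `(i dx, j dy, k dz)` has Euclidean norm at most `radius_mm`. Always
#' contains `(0, 0, 0)` and is symmetric under negation.
#'
#' @param radius_mm Sphere radius, mm.
#' @param voxel_size_mm Voxel edge lengths, mm (triple).
#' @return Integer matrix with one offset per row.
#' @examples
#' nrow(sphere_offsets(1.4, c(1.4, 1.4, 2.0)))   # 5: z neighbors lie 2 mm away
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm) {
  stopifnot(radius_mm >= 0, length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  r <- floor(radius_mm / voxel_size_mm)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (g$i * voxel_size_mm[1])^2 + (g$j * voxel_size_mm[2])^2 +
    (g$k * voxel_size_mm[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

#' Leave-one-run-out cross-validation folds
#'
#' Each run is held out as the test set exactly once, in sorted order; with 8
#' runs this is the 8-fold leave-one-out splitter of the decoding analysis.
#'
#' @param run_ids Vector of run identifiers (at least 2 distinct).
#' @return List of folds, each `list(train, test)`.
#' @export
leave_one_run_out_folds <- function(run_ids) {
  runs <- sort(unique(run_ids))
  if (length(runs) < 2) stop("need at least 2 runs for cross-validation")
  lapply(runs, function(r) list(train = setdiff(runs, r), test = r))
}

#' Cross-validated pairwise classification accuracy
#'
#' Trains a soft-margin linear SVM on the training folds' pattern vectors and
#' scores the held-out vectors; fold accuracies (each over 2 test patterns
#' with leave-one-run-out folds, hence in {0, 0.5, 1}) are averaged. All
#' features enter as given — no selection, no scaling unless
#' `config$zscore`. A test pattern exactly on the decision boundary is
#' assigned to the lexicographically first category.
#'
#' @param features Numeric matrix, one pattern vector per row.
#' @param labels Category label per row (exactly 2 distinct values).
#' @param run_ids Run identifier per row.
#' @param folds Folds as from [leave_one_run_out_folds()] (the default).
#' @param config A [searchlight_config()] (only `svm_cost` and `zscore`
#'   matter here).
#' @return Mean accuracy over folds, in `[0, 1]`.
#' @export
classify_pair_cv <- function(features, labels, run_ids,
                             folds = leave_one_run_out_folds(run_ids),
                             config = searchlight_config()) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite feature values")
  cats <- sort(unique(as.character(labels)))
  if (length(cats) != 2) stop("exactly two categories required")
  y <- ifelse(as.character(labels) == cats[1], 1L, -1L)
  acc <- vapply(folds, function(fold) {
    tr <- which(run_ids %in% fold$train)
    te <- which(run_ids %in% fold$test)
    if (!length(tr) || !length(te)) stop("empty fold")
    Xtr <- features[tr, , drop = FALSE]
    Xte <- features[te, , drop = FALSE]
    if (config$zscore) {
      mu <- colMeans(Xtr)
      s <- apply(Xtr, 2, sd)
      s[s == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, s, "/")
    }
    G <- tcrossprod(Xtr)
    mod <- .svm_train_gram_cpp(G, y[tr], config$svm_cost)
    f <- drop(Xte %*% crossprod(Xtr, mod$alpha * y[tr])) + mod$b
    pred <- ifelse(f < 0, -1L, 1L)
    mean(pred == y[te])
  }, numeric(1))
  mean(acc)
}

#' Whole-brain searchlight accuracy map
#'
#' For every in-mask voxel, gathers the beta vectors of the two categories
#' across runs from the sphere centered there (intersected with the mask),
#' runs leave-one-run-out cross-validated linear SVM classification, and
#' assigns the mean accuracy to the center voxel. Deterministic given its
#' inputs and independent of traversal order.
#'
#' @param betas A `beta_images` object from [fit_glm()].
#' @param pair Character pair of category names, e.g. `c("face", "object")`.
#' @param mask 3-D logical analysis mask.
#' @param config A [searchlight_config()].
#' @param voxel_size_mm Voxel sizes; required to turn the radius into offsets.
#' @return List of class `accuracy_map`: `data` (3-D array, accuracies in
#'   `[0, 1]` inside the mask, `NA` elsewhere), `pair`, `config`, `n_folds`.
#' @export
searchlight_map <- function(betas, pair, mask, config = searchlight_config(),
                            voxel_size_mm = c(1.4, 1.4, 2.0)) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  if (!any(mask)) stop("empty mask")
  dims <- betas$grid_dims
  stopifnot(all(dim(mask) == dims))
  sel <- betas$condition %in% pair
  if (!any(sel)) stop("betas lack the requested categories")
  runs <- sort(unique(betas$run[sel]))
  cats <- sort(pair)
  # sample order: (run 1, cat A), (run 1, cat B), (run 2, cat A), ...
  idx <- integer(0); y <- integer(0); run_lab <- integer(0)
  for (r in runs) for (ci in seq_along(cats)) {
    m <- which(betas$condition == cats[ci] & betas$run == r)
    if (length(m) != 1) stop("need exactly one beta map per (category, run)")
    idx <- c(idx, m); y <- c(y, if (ci == 1) 1L else -1L)
    run_lab <- c(run_lab, r)
  }
  vox <- which(mask)
  flat <- matrix(betas$data, prod(dims), length(betas$condition))
  B <- t(flat[vox, idx, drop = FALSE])              # n_samples x n_inmask
  if (any(!is.finite(B))) stop("non-finite beta values inside the mask")
  vox2col <- rep(-1L, prod(dims))
  vox2col[vox] <- seq_along(vox) - 1L
  off <- sphere_offsets(config$radius_mm, voxel_size_mm)
  if (config$zscore) {
    acc <- sl_map_zscore_r(B, y, run_lab, vox2col, dims, off, vox, config)
  } else {
    acc <- .sl_map_cpp(B, y, run_lab, vox2col, as.integer(dims),
                       off, vox - 1L, config$svm_cost,
                       config$min_sphere_voxels)
  }
  data <- array(NA_real_, dims)
  data[vox] <- acc
  structure(list(data = data, pair = pair, config = config,
                 n_folds = length(runs)),
            class = "accuracy_map")
}

# Slow-path map with per-fold feature standardization (sensitivity analyses)
sl_map_zscore_r <- function(B, y, run_lab, vox2col, dims, off, vox, config) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vapply(seq_along(vox), function(ci) {
    lin <- vox[ci] - 1L
    cx <- lin %% nx; cy <- (lin %/% nx) %% ny; cz <- lin %/% (nx * ny)
    x <- cx + off[, 1]; yy <- cy + off[, 2]; z <- cz + off[, 3]
    ok <- x >= 0 & x < nx & yy >= 0 & yy < ny & z >= 0 & z < nz
    cols <- vox2col[x[ok] + nx * (yy[ok] + ny * z[ok]) + 1L] + 1L
    cols <- cols[cols > 0]
    if (length(cols) < config$min_sphere_voxels) return(NA_real_)
    classify_pair_cv(B[, cols, drop = FALSE], ifelse(y == 1L, "a", "b"),
                     run_lab, config = config)
  }, numeric(1))
}
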