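# Shared fixtures: all synthetic, generated in code at test time.

# Small geometry for fast end-to-end tests
tiny_geometry <- function(n_runs = 2L, n_volumes = 56L) {
  acq_geometry(grid_dims = c(8L, 8L, 6L), voxel_size_mm = c(1.4, 1.4, 2.0),
               tr_s = 3, n_volumes_per_run = n_volumes, n_runs = n_runs)
}

tiny_truth <- function(geometry, ...) {
  make_ground_truth(
    geometry,
    roi_specs = list(roi_a = list(center_vox = c(3L, 3L, 3L), radius_mm = 3)),
    brain_mask = array(TRUE, geometry$grid_dims), ...)
}

noiseless <- function() noise_params(white_sd = 0, drift_amplitude = 0,
                                     ar1_coefficient = 0)

# Independent searchlight oracle: plain triple loop over voxels, spheres by
# direct distance test, per-fold linear SVM via e1071 (libsvm), accuracy
# averaged over leave-one-run-out folds.
naive_searchlight <- function(betas, pair, mask, radius_mm, voxel_size_mm,
                              cost = 1, min_vox = 2L) {
  dims <- betas$grid_dims
  runs <- sort(unique(betas$run))
  cats <- sort(pair)
  flat <- matrix(betas$data, prod(dims), length(betas$condition))
  samp <- expand.grid(cat = cats, run = runs, stringsAsFactors = FALSE)
  cols <- mapply(function(cc, rr) which(betas$condition == cc & betas$run == rr),
                 samp$cat, samp$run)
  out <- array(NA_real_, dims)
  coords <- which(mask, arr.ind = TRUE)
  all_idx <- which(mask)
  all_xyz <- which(array(TRUE, dims), arr.ind = TRUE)
  for (v in seq_len(nrow(coords))) {
    cv <- coords[v, ]
    d2 <- ((all_xyz[, 1] - cv[1]) * voxel_size_mm[1])^2 +
      ((all_xyz[, 2] - cv[2]) * voxel_size_mm[2])^2 +
      ((all_xyz[, 3] - cv[3]) * voxel_size_mm[3])^2
    sphere <- intersect(which(d2 <= radius_mm^2 + 1e-9), all_idx)
    if (length(sphere) < min_vox) next
    X <- t(flat[sphere, cols, drop = FALSE])
    lab <- factor(samp$cat, levels = cats)
    accs <- vapply(runs, function(tr_out) {
      tr <- samp$run != tr_out
      # tight tolerance: near-boundary test points need well-converged
      # decision values for sign agreement
      fit <- e1071::svm(X[tr, , drop = FALSE], lab[tr], kernel = "linear",
                        cost = cost, scale = FALSE, tolerance = 1e-7)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      mean(pred == lab[!tr])
    }, numeric(1))
    out[cv[1], cv[2], cv[3]] <- mean(accs)
  }
  out
}

# Beta images built directly from a matrix of pattern vectors (bypasses the
# GLM) -- for classifier-level tests
betas_from_matrix <- function(M, conditions, runs, dims, mask) {
  n_maps <- nrow(M)
  data <- array(NA_real_, c(dims, n_maps))
  flat <- matrix(data, prod(dims), n_maps)
  flat[which(mask), ] <- t(M)
  structure(list(data = array(flat, c(dims, n_maps)),
                 condition = conditions, run = runs,
                 mask = mask, grid_dims = dims),
            class = "beta_images")
}
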