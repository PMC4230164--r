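test_that("sphere offsets respect anisotropic voxel sizes", {
  vs <- c(1.4, 1.4, 2.0)
  expect_equal(sphere_offsets(0, vs), cbind(i = 0L, j = 0L, k = 0L),
               ignore_attr = TRUE)
  # radius 1.4 mm: in-plane neighbors included, 2.0-mm z neighbors excluded
  off <- sphere_offsets(1.4, vs)
  expect_equal(nrow(off), 5)
  expect_true(all(off[, 3] == 0))
  # exhaustive enumeration oracle at the analysis radius
  r <- 10
  cnt <- 0L
  for (i in -7:7) for (j in -7:7) for (k in -5:5) {
    if ((i * 1.4)^2 + (j * 1.4)^2 + (k * 2)^2 <= r^2) cnt <- cnt + 1L
  }
  off10 <- sphere_offsets(r, vs)
  expect_equal(nrow(off10), cnt)
  # symmetry under negation, center always present
  key <- function(m) sort(unname(apply(m, 1, paste, collapse = ",")))
  expect_equal(key(off10), key(-off10))
  expect_true(any(rowSums(abs(off10)) == 0))
})

test_that("leave-one-run-out folds partition the runs", {
  folds <- leave_one_run_out_folds(1:8)
  expect_length(folds, 8)
  expect_setequal(vapply(folds, `[[`, 0, "test"), 1:8)
  for (f in folds) {
    expect_length(f$train, 7)
    expect_length(intersect(f$train, f$test), 0)
  }
  f2 <- leave_one_run_out_folds(c(4, 2))
  expect_length(f2, 2)
  expect_equal(f2[[1]]$test, 2)
  expect_error(leave_one_run_out_folds(rep(1, 3)), "at least 2")
})

test_that("classifier is perfect on separable data and chance on noise", {
  set.seed(1)
  n_runs <- 8
  lab <- rep(c("face", "object"), n_runs)
  run <- rep(1:n_runs, each = 2)
  sep <- matrix(rnorm(16 * 10, sd = 0.05), 16)
  sep[lab == "face", ] <- sep[lab == "face", ] + 3
  expect_equal(classify_pair_cv(sep, lab, run), 1.0)

  accs <- replicate(60, {
    classify_pair_cv(matrix(rnorm(16 * 10), 16), sample(lab), run)
  })
  # fold accuracies in {0, .5, 1} make 16 x mean accuracy an integer
  expect_true(all(abs(accs * 16 - round(accs * 16)) < 1e-9))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.01)
})

test_that("classifier decisions match the reference libsvm implementation", {
  set.seed(7)
  lab <- rep(c("a", "b"), 6)
  run <- rep(1:6, each = 2)
  for (rep_i in 1:25) {
    X <- matrix(rnorm(12 * 8, sd = sample(c(0.3, 1, 3), 1)), 12)
    X[lab == "a", ] <- X[lab == "a", ] + rnorm(1, sd = 1)
    mine <- classify_pair_cv(X, lab, run)
    ref <- mean(vapply(1:6, function(r) {
      tr <- run != r
      fit <- e1071::svm(X[tr, ], factor(lab[tr]), kernel = "linear",
                        cost = 1, scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == lab[!tr])
    }, numeric(1)))
    expect_equal(mine, ref)
  }
})

test_that("searchlight map equals the naive triple-loop oracle", {
  set.seed(5)
  dims <- c(6L, 6L, 4L)
  vs <- c(1.4, 1.4, 2.0)
  mask <- array(TRUE, dims)
  mask[1, 1, ] <- FALSE                      # ragged mask edge
  n_runs <- 4
  conds <- rep(c("face", "object"), n_runs)
  runs <- rep(1:n_runs, each = 2)
  M <- matrix(rnorm(length(conds) * sum(mask)), length(conds))
  M[conds == "face", ] <- M[conds == "face", ] + 0.8
  betas <- betas_from_matrix(M, conds, runs, dims, mask)
  cfg <- searchlight_config(radius_mm = 3)
  mine <- searchlight_map(betas, c("face", "object"), mask, cfg, vs)
  oracle <- naive_searchlight(betas, c("face", "object"), mask, 3, vs)
  expect_equal(mine$data, oracle)
})

test_that("swapping the category labels leaves the accuracy map unchanged", {
  set.seed(9)
  dims <- c(5L, 5L, 4L)
  mask <- array(TRUE, dims)
  conds <- rep(c("face", "object"), 4)
  runs <- rep(1:4, each = 2)
  M <- matrix(rnorm(8 * prod(dims)), 8)
  betas <- betas_from_matrix(M, conds, runs, dims, mask)
  a <- searchlight_map(betas, c("face", "object"), mask,
                       searchlight_config(radius_mm = 3))
  b <- searchlight_map(betas, c("object", "face"), mask,
                       searchlight_config(radius_mm = 3))
  expect_identical(a$data, b$data)
})

test_that("a single-voxel mask yields one scalar-feature accuracy", {
  dims <- c(4L, 4L, 3L)
  mask <- array(FALSE, dims); mask[2, 2, 2] <- TRUE
  set.seed(2)
  conds <- rep(c("face", "object"), 4)
  runs <- rep(1:4, each = 2)
  M <- matrix(rnorm(8), 8, 1)
  betas <- betas_from_matrix(M, conds, runs, dims, mask)
  cfg <- searchlight_config(radius_mm = 5, min_sphere_voxels = 1L)
  am <- searchlight_map(betas, c("face", "object"), mask, cfg)
  expect_equal(sum(!is.na(am$data)), 1)
  expect_equal(am$data[2, 2, 2],
               classify_pair_cv(M, conds, runs, config = cfg))
  # spheres below min_sphere_voxels stay NA
  cfg2 <- searchlight_config(radius_mm = 5, min_sphere_voxels = 2L)
  am2 <- searchlight_map(betas, c("face", "object"), mask, cfg2)
  expect_true(all(is.na(am2$data)))
})

test_that("null beta patterns decode at chance on average across subjects", {
  set.seed(31)
  dims <- c(6L, 6L, 4L)
  mask <- array(TRUE, dims)
  conds <- rep(c("face", "object"), 4)
  runs <- rep(1:4, each = 2)
  n_sub <- 50
  grand <- rowMeans(vapply(seq_len(n_sub), function(s) {
    M <- matrix(rnorm(8 * prod(dims)), 8)
    am <- searchlight_map(betas_from_matrix(M, conds, runs, dims, mask),
                          c("face", "object"), mask,
                          searchlight_config(radius_mm = 3))
    as.vector(am$data)
  }, numeric(prod(dims))))
  # across-subject mean accuracy per voxel: binomial-ish standard error with
  # n = 2 x runs observations per subject map
  se <- sqrt(0.25 / (2 * 4)) / sqrt(n_sub)
  expect_lt(max(abs(grand - 0.5)), 5 * se)
  expect_lt(abs(mean(grand) - 0.5), 3 * se)
})

test_that("regional accuracy rises with the implanted pattern amplitude", {
  geom <- tiny_geometry(n_runs = 4L)
  design <- make_design(geom)
  amps <- c(0.2, 0.6, 1.8)
  mean_acc <- vapply(amps, function(a) {
    mean(vapply(1:20, function(s) {
      truth <- tiny_truth(geom, pattern_sd = a, seed = s)
      runs <- simulate_subject(design, truth, "control",
                               noise_params(white_sd = 1.2), 1000 + s)
      betas <- fit_subject_glm(runs, design, truth$brain_mask, fwhm_mm = 0)
      am <- searchlight_map(betas, c("face", "object"), truth$brain_mask,
                            searchlight_config(radius_mm = 4),
                            geom$voxel_size_mm)
      mean(am$data[truth$roi_masks[[1]]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) > 0))
  expect_gt(mean_acc[3], 0.9)
})

test_that("per-fold z-scoring path agrees with the raw path contract", {
  set.seed(12)
  dims <- c(4L, 4L, 3L)
  mask <- array(TRUE, dims)
  conds <- rep(c("face", "object"), 4)
  runs <- rep(1:4, each = 2)
  M <- matrix(rnorm(8 * prod(dims)), 8)
  M[conds == "face", ] <- M[conds == "face", ] + 1
  betas <- betas_from_matrix(M, conds, runs, dims, mask)
  am <- searchlight_map(betas, c("face", "object"), mask,
                        searchlight_config(radius_mm = 3, zscore = TRUE))
  expect_true(all(am$data >= 0 & am$data <= 1))
  expect_equal(dim(am$data), dims)
})
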