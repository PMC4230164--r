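test_that("design matrix has one column per (category, run) plus run means", {
  X <- build_design_matrix(make_design())
  expect_equal(dim(X$values), c(8 * 112, 4 * 8 + 8))
  expect_equal(sum(is.na(X$condition)), 8)       # run-mean columns
  expect_equal(sum(!is.na(X$condition)), 32)
  # condition regressors are causal: zero before their first block onset
  d <- make_design()
  for (j in which(!is.na(X$condition))[c(1, 9, 20)]) {
    r <- X$run[j]
    ev <- d$events[d$events$run == r & d$events$condition == X$condition[j], ]
    onset_scan <- floor(min(ev$onset) / 3)
    rows <- (r - 1) * 112 + seq_len(112)
    col <- X$values[rows, j]
    if (onset_scan >= 1) expect_equal(max(abs(col[seq_len(onset_scan)])), 0)
    expect_gt(max(col), 0)
  }
})

test_that("noiseless GLM recovers the implanted response maps", {
  geom <- tiny_geometry(n_runs = 3L)
  for (subject_specific in c(TRUE, FALSE)) {
    truth <- tiny_truth(geom, subject_specific = subject_specific, seed = 9)
    runs <- simulate_subject(make_design(geom), truth, "cp", noiseless(),
                             subject_seed = 21)
    betas <- fit_subject_glm(runs, make_design(geom), truth$brain_mask,
                             fwhm_mm = 0)
    resp <- subject_response_maps(truth, "cp", 21)
    for (cat in c("face", "object")) for (r in 1:3) {
      expect_lt(max(abs(beta_map(betas, cat, r) - resp[[cat]])),
                1e-6 * truth$mean_amplitude)
    }
  }
})

test_that("doubling the implanted amplitude doubles the fitted betas", {
  geom <- tiny_geometry()
  design <- make_design(geom)
  t1 <- tiny_truth(geom, mean_amplitude = 1, pattern_sd = 0.4, seed = 4,
                   subject_specific = FALSE)
  t2 <- tiny_truth(geom, mean_amplitude = 2, pattern_sd = 0.8, seed = 4,
                   subject_specific = FALSE)
  b1 <- fit_subject_glm(simulate_subject(design, t1, "control", noiseless(), 8),
                        design, t1$brain_mask, fwhm_mm = 0)
  b2 <- fit_subject_glm(simulate_subject(design, t2, "control", noiseless(), 8),
                        design, t2$brain_mask, fwhm_mm = 0)
  expect_equal(beta_map(b2, "face", 1), 2 * beta_map(b1, "face", 1),
               tolerance = 1e-10)
})

test_that("pure-noise betas are mean-zero and run relabeling is a symmetry", {
  geom <- tiny_geometry(n_runs = 2L)
  design <- make_design(geom)
  truth <- tiny_truth(geom, mean_amplitude = 0, pattern_sd = 0, seed = 2)
  runs <- simulate_subject(design, truth, "control",
                           noise_params(white_sd = 1, drift_amplitude = 0,
                                        ar1_coefficient = 0), 5)
  betas <- fit_glm(runs, build_design_matrix(design), truth$brain_mask)
  all_b <- betas$data[!is.na(betas$data)]
  expect_lt(abs(mean(all_b)), 4 * sd(all_b) / sqrt(length(all_b)))

  # swapping both the data runs and the design's run labels permutes betas
  design_sw <- design
  ev <- design$events
  ev$run <- c(2L, 1L)[ev$run]
  design_sw$events <- ev[order(ev$run, ev$onset), ]
  betas_sw <- fit_glm(runs[c(2, 1)], build_design_matrix(design_sw),
                      truth$brain_mask)
  expect_equal(beta_map(betas_sw, "face", 1), beta_map(betas, "face", 2),
               tolerance = 1e-10)
  expect_equal(beta_map(betas_sw, "object", 2), beta_map(betas, "object", 1),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are reported with the offending columns", {
  geom <- tiny_geometry(n_runs = 2L)
  design <- make_design(geom)
  X <- build_design_matrix(design)
  j <- which(!is.na(X$condition) & X$condition == "object" & X$run == 1)
  k <- which(!is.na(X$condition) & X$condition == "face" & X$run == 1)
  X$values[, j] <- X$values[, k]        # duplicate a regressor
  runs <- simulate_subject(design, tiny_truth(geom, seed = 1), "control",
                           noiseless(), 1)
  expect_error(fit_glm(runs, X, array(TRUE, geom$grid_dims)),
               "rank-deficient")
})

test_that("contrasts are linear and match the implanted pattern difference", {
  geom <- tiny_geometry(n_runs = 2L)
  design <- make_design(geom)
  truth <- tiny_truth(geom, seed = 31, subject_specific = FALSE)
  runs <- simulate_subject(design, truth, "control", noiseless(), 3)
  betas <- fit_subject_glm(runs, design, truth$brain_mask, fwhm_mm = 0)
  w_fo <- c(face = 1, object = -1, body = 0, body_part = 0)
  con <- compute_contrast(betas, w_fo)
  resp <- group_response_maps(truth, "control")
  implanted <- resp$face - resp$object
  expect_equal(con[truth$brain_mask], implanted[truth$brain_mask],
               tolerance = 1e-8)
  # mean-amplitude matching: regional mean of the contrast is zero
  roi <- truth$roi_masks[[1]]
  expect_lt(abs(mean(con[roi])), 1e-10)
  # linearity: all-zero weights, and sign flip
  zero <- compute_contrast(betas, c(face = 0, object = 0, body = 0,
                                    body_part = 0))
  expect_equal(max(abs(zero[truth$brain_mask])), 0)
  neg <- compute_contrast(betas, -w_fo)
  expect_equal(neg[truth$brain_mask], -con[truth$brain_mask])
  expect_error(compute_contrast(betas, c(face = 1)), "missing")
})
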