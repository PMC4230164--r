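as_maps <- function(M, dims) {
  lapply(seq_len(nrow(M)), function(i) array(M[i, ], dims))
}

test_that("one-sample t matches hand computation and flags zero variance", {
  dims <- c(2L, 2L, 1L)
  vals <- c(0.6, 0.7, 0.8)
  maps <- lapply(vals, function(v) array(v, dims))
  sm <- one_sample_t_map(maps, null_value = 0.5)
  expect_equal(sm$data[1, 1, 1], (0.7 - 0.5) / (0.1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(sm$df, 2)

  flat <- lapply(1:3, function(i) array(0.5, dims))
  sm0 <- one_sample_t_map(flat, 0.5)
  expect_true(all(is.na(sm0$data)))
  expect_equal(sm0$n_zero_variance, prod(dims))

  # translation equivariance: adding c to all maps == shifting the null by -c
  set.seed(4)
  M <- matrix(rnorm(5 * 4), 5)
  a <- one_sample_t_map(M + 0.2, null_value = 0.5)
  b <- one_sample_t_map(M, null_value = 0.3)
  expect_equal(a$data, b$data, tolerance = 1e-12)
  expect_error(one_sample_t_map(M[1, , drop = FALSE]), "at least 2")
})

test_that("two-sample t matches hand computation and is antisymmetric", {
  dims <- c(1L, 1L, 1L)
  A <- as_maps(matrix(c(1, 2, 3)), dims)
  B <- as_maps(matrix(c(2, 3, 4)), dims)
  sm <- two_sample_t_map(A, B)
  expect_equal(sm$data[1, 1, 1], -1.2247449, tolerance = 1e-6)
  expect_equal(sm$df, 4)
  expect_equal(two_sample_t_map(B, A)$data[1, 1, 1], -sm$data[1, 1, 1])
  expect_equal(two_sample_t_map(A, A)$data[1, 1, 1], 0)
})

test_that("t maps agree with the reference t.test on random voxels", {
  set.seed(8)
  n_vox <- 1000
  A <- matrix(rnorm(10 * n_vox), 10)
  B <- matrix(rnorm(7 * n_vox, mean = 0.2), 7)
  one <- one_sample_t_map(A, null_value = 0.1)
  pooled <- two_sample_t_map(A, B, equal_variance = TRUE)
  welch <- two_sample_t_map(A, B, equal_variance = FALSE)
  for (v in sample(n_vox, 40)) {
    expect_equal(one$data[v], unname(t.test(A[, v], mu = 0.1)$statistic),
                 tolerance = 1e-10)
    expect_equal(pooled$data[v],
                 unname(t.test(A[, v], B[, v], var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    ref <- t.test(A[, v], B[, v])
    expect_equal(welch$data[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(welch$df_map[v], unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("critical t values match tabled quantiles", {
  expect_equal(critical_t(0.5, 7), 0)
  expect_equal(round(critical_t(0.001, 15), 2), 3.73)
  expect_equal(critical_t(0.025, 1e6), 1.960, tolerance = 1e-3)
  expect_gt(critical_t(0.001, 15, "two_sided"), critical_t(0.001, 15))
  expect_error(critical_t(0, 10), "in \\(0, 1\\)")
  expect_error(critical_t(1.2, 10))
})

test_that("clusters split and merge according to connectivity", {
  dims <- c(3L, 3L, 3L)
  arr <- array(0, dims)
  arr[1, 1, 1] <- 5
  arr[2, 2, 2] <- 4          # touches (1,1,1) only at a corner
  sm <- structure(list(data = arr, df = 10, test = "x"), class = "stat_map")
  expect_equal(nrow(extract_clusters(sm, 3, connectivity = 26)), 1)
  t6 <- extract_clusters(sm, 3, connectivity = 6)
  expect_equal(nrow(t6), 2)
  expect_equal(t6$peak_stat, c(5, 4))          # sorted by peak, descending
  expect_equal(t6$extent, c(1L, 1L))
  # edge-touching voxels merge under 18 but not 6
  arr2 <- array(0, dims); arr2[1, 1, 1] <- 5; arr2[2, 2, 1] <- 4
  sm2 <- structure(list(data = arr2, df = 10, test = "x"), class = "stat_map")
  expect_equal(nrow(extract_clusters(sm2, 3, connectivity = 18)), 1)
  expect_equal(nrow(extract_clusters(sm2, 3, connectivity = 6)), 2)
  # below threshold everywhere -> empty table
  expect_equal(nrow(extract_clusters(sm, 10)), 0)
  # world coordinates via the affine
  geom <- acq_geometry(grid_dims = dims, voxel_size_mm = c(2, 2, 2))
  tab <- extract_clusters(sm, 4.5, geometry = geom)
  expect_equal(c(tab$x_mm, tab$y_mm, tab$z_mm), c(-2, -2, -2))
})

test_that("permutation p-values honour the identity-permutation bound", {
  set.seed(21)
  dims <- c(4L, 4L, 3L)
  # localized overwhelming effect in a 2x2x2 block, weak noise elsewhere
  block <- array(FALSE, dims); block[1:2, 1:2, 1:2] <- TRUE
  M <- matrix(rnorm(8 * prod(dims), sd = 0.3), 8)
  M[, as.vector(block)] <- M[, as.vector(block)] + 20
  # seed chosen so no random draw duplicates the all-plus sign pattern,
  # keeping the extreme case clean (duplicates of the identity are legal and
  # simply tie)
  res <- permutation_correct(maps = as_maps(M, dims), scheme = "sign_flip",
                             n_permutations = 199, seed = 1)
  expect_gte(min(res$cluster_table$p_corrected), 1 / (1 + 199))
  # the observed cluster out-sizes every permutation -> exactly the bound
  expect_equal(min(res$cluster_table$p_corrected), 1 / (1 + 199))
  # voxel-level: the observed peak exceeds every permutation's max statistic
  peak <- max(res$observed$data, na.rm = TRUE)
  expect_equal((1 + sum(res$max_stat_null[-1] >= peak)) / (1 + 199),
               1 / (1 + 199))
  expect_error(permutation_correct(maps = as_maps(M, dims),
                                   n_permutations = 50), "at least 100")
  expect_error(permutation_correct(maps = as_maps(M, dims),
                                   cluster_forming_p = 2,
                                   n_permutations = 100))
})

test_that("familywise error of cluster correction is calibrated under the null", {
  set.seed(77)
  dims <- c(8L, 8L, 5L)
  n_cohorts <- 200
  n_a <- 8; n_b <- 6
  hits05 <- 0; hits01 <- 0
  for (i in seq_len(n_cohorts)) {
    # label-exchangeable null: all subjects drawn from one distribution,
    # spatially smoothed so clusters can form
    subj <- lapply(seq_len(n_a + n_b), function(s) {
      gaussian_smooth(array(rnorm(prod(dims)), dims), 3, c(1.4, 1.4, 2))
    })
    res <- permutation_correct(maps_a = subj[seq_len(n_a)],
                               maps_b = subj[n_a + seq_len(n_b)],
                               scheme = "label_shuffle",
                               n_permutations = 199, seed = i,
                               cluster_forming_p = 0.01)
    if (nrow(res$cluster_table)) {
      p <- min(res$cluster_table$p_corrected)
      hits05 <- hits05 + (p <= 0.05)
      hits01 <- hits01 + (p <= 0.01)
    }
  }
  se05 <- sqrt(0.05 * 0.95 / n_cohorts)
  se01 <- sqrt(0.01 * 0.99 / n_cohorts)
  expect_lt(hits05 / n_cohorts, 0.05 + 3 * se05)
  expect_lt(hits01 / n_cohorts, 0.01 + 3 * se01)
  expect_gt(hits05 / n_cohorts, 0.05 - 3 * se05)
})
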