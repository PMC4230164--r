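#' Noise model parameters
#'
#' @param white_sd Standard deviation of the white-noise innovations (signal
#'   units; the simulated block response amplitude is 1 by default, so this is
#'   roughly noise-to-signal).
#' @param drift_amplitude Temporal standard deviation of the slow scanner
#'   drift: per voxel and run, a random combination of cosine components
#'   with periods of 160 s and longer. A high-pass cutoff of 128 s or more
#'   removes this band entirely; shorter-period drift is deliberately not
#'   simulated.
#' @param ar1_coefficient Temporal autocorrelation of the noise, in `[0, 1)`;
#'   white innovations are passed through a first-order autoregressive filter.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(white_sd = 1.2, drift_amplitude = 1,
                         ar1_coefficient = 0.3) {
  stopifnot(is.finite(white_sd), white_sd >= 0,
            is.finite(drift_amplitude), drift_amplitude >= 0,
            is.finite(ar1_coefficient), ar1_coefficient >= 0, ar1_coefficient < 1)
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 ar1_coefficient = ar1_coefficient),
            class = "noise_params")
}

#' Simulate one subject's 4-D runs
#'
#' Every voxel's time course is
#' `baseline + sum_categories(response_map * HRF-convolved boxcar) + drift +
#' AR(1)-filtered Gaussian noise`. The condition regressors are exactly those
#' the GLM later fits ([build_design_matrix()]), so with zero noise the GLM
#' recovers the implanted response maps to machine precision. CP subjects get
#' the separability-shrunk face/object patterns of [group_response_maps()].
#'
#' @param design An [make_design()] design.
#' @param truth A [make_ground_truth()] object on the same geometry.
#' @param group `"control"` or `"cp"`.
#' @param noise A [noise_params()] set.
#' @param subject_seed Integer; fully determines this subject's noise.
#' @param baseline Constant signal offset (arbitrary units).
#' @param hrf HRF parameters (shared with the GLM by default).
#' @return List of 4-D arrays (x, y, z, time), one per run.
#' @export
simulate_subject <- function(design, truth, group = c("control", "cp"),
                             noise = noise_params(), subject_seed = 1L,
                             baseline = 100, hrf = hrf_params()) {
  group <- match.arg(group)
  geom <- design$geometry
  if (!all(geom$grid_dims == truth$geometry$grid_dims)) {
    stop("design and truth geometries disagree")
  }
  if (!all(is.finite(c(noise$white_sd, noise$drift_amplitude,
                       noise$ar1_coefficient, baseline)))) {
    stop("non-finite simulation parameters")
  }
  resp <- subject_response_maps(truth, group, subject_seed)
  X <- build_design_matrix(design, hrf)
  n_scan <- X$n_scans_per_run
  n_vox <- prod(geom$grid_dims)
  # n_vox x n_cat matrix of implanted response amplitudes
  W <- vapply(design$condition_names, function(cat) as.vector(resp[[cat]]),
              numeric(n_vox))
  set.seed(as.integer(subject_seed))
  runs <- vector("list", geom$n_runs)
  scan_t <- (seq_len(n_scan) - 1) * geom$tr_s
  for (r in seq_len(geom$n_runs)) {
    rows <- (r - 1) * n_scan + seq_len(n_scan)
    jr <- which(!is.na(X$condition) & X$run == r)
    Xr <- X$values[rows, jr, drop = FALSE]          # n_scan x n_cat
    sig <- tcrossprod(W, Xr)                        # n_vox x n_scan
    sig <- sig + baseline
    if (noise$drift_amplitude > 0) {
      Bd <- drift_basis(n_scan, geom$tr_s)
      coef <- matrix(rnorm(n_vox * ncol(Bd),
                           sd = noise$drift_amplitude / sqrt(ncol(Bd))),
                     ncol(Bd), n_vox)
      sig <- sig + t(Bd %*% coef)
    }
    if (noise$white_sd > 0) {
      eps <- matrix(rnorm(n_vox * n_scan, sd = noise$white_sd), n_scan, n_vox)
      if (noise$ar1_coefficient > 0) {
        eps <- stats::filter(eps, noise$ar1_coefficient,
                             method = "recursive")
        eps <- matrix(as.numeric(eps), n_scan, n_vox)
      }
      sig <- sig + t(eps)
    }
    runs[[r]] <- array(sig, c(geom$grid_dims, n_scan))
  }
  runs
}

# Slow-drift basis: cosine components with period >= 160 s, columns scaled
# to unit temporal standard deviation
drift_basis <- function(n_scan, tr_s, min_period_s = 160) {
  k_max <- max(1L, floor(2 * n_scan * tr_s / min_period_s))
  t <- 0:(n_scan - 1)
  B <- vapply(seq_len(k_max),
              function(k) cos(pi * k * (2 * t + 1) / (2 * n_scan)),
              numeric(n_scan))
  sweep(B, 2, apply(B, 2, sd), "/")
}

#' Cohort specification
#'
#' Bundles everything that defines a synthetic two-group cohort. Defaults
#' follow the emulated study: 10 controls and 7 congenital-prosopagnosia (CP)
#' subjects, 8 runs each.
#'
#' @param n_controls,n_cps Group sizes (each at least 2).
#' @param design Experiment design shared by all subjects.
#' @param truth Generative ground truth.
#' @param noise Noise parameters.
#' @param seed Master seed; per-subject seeds are derived as
#'   `seed * 1000 + subject_index`.
#' @param baseline Constant signal offset.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 10L, n_cps = 7L,
                        design = make_design(),
                        truth = make_ground_truth(design$geometry),
                        noise = noise_params(), seed = 1L, baseline = 100) {
  stopifnot(n_controls >= 2, n_cps >= 2)
  structure(list(n_controls = as.integer(n_controls), n_cps = as.integer(n_cps),
                 design = design, truth = truth, noise = noise,
                 seed = as.integer(seed), baseline = baseline),
            class = "cohort_spec")
}

cohort_groups <- function(spec) {
  c(rep("control", spec$n_controls), rep("cp", spec$n_cps))
}

subject_seed_for <- function(spec, i) spec$seed * 1000L + i

#' Simulate a cohort in memory
#'
#' @param spec A [cohort_spec()].
#' @return List with `spec`, `groups`, and `subjects` (list of per-subject
#'   run lists).
#' @export
simulate_cohort_mem <- function(spec) {
  groups <- cohort_groups(spec)
  subjects <- lapply(seq_along(groups), function(i) {
    simulate_subject(spec$design, spec$truth, groups[i], spec$noise,
                     subject_seed = subject_seed_for(spec, i),
                     baseline = spec$baseline)
  })
  list(spec = spec, groups = groups, subjects = subjects)
}
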