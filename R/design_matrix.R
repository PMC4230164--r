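#' Build the GLM design matrix for a block design
#'
#' One regressor per (stimulus category, run): the run's 0/1 boxcar for that
#' category, convolved with the canonical HRF on a fine time grid and sampled
#' at scan acquisition times; one constant regressor per run models the run
#' mean. Fixation blocks are deliberately unmodeled, so condition estimates
#' are expressed relative to the fixation baseline.
#'
#' @param design An [make_design()] experiment design.
#' @param hrf A [hrf_params()] parameter set.
#' @param dt_s Fine-grid step used for the convolution, seconds.
#' @return A list of class `design_matrix`: `values` (n_scans x n_regressors),
#'   `condition` and `run` labels per column (`NA` condition marks run-mean
#'   columns), and `frame_times_s`.
#' @examples
#' X <- build_design_matrix(make_design())
#' dim(X$values)   # 896 x 40: 4 categories x 8 runs + 8 run means
#' @export
build_design_matrix <- function(design, hrf = hrf_params(), dt_s = 0.1) {
  geom <- design$geometry
  if (any(!(design$events$run %in% seq_len(geom$n_runs)))) {
    stop("events reference runs outside the geometry")
  }
  n_scan <- geom$n_volumes_per_run
  scan_t <- (seq_len(n_scan) - 1) * geom$tr_s
  h <- canonical_hrf(dt_s, hrf)
  cats <- design$condition_names
  cols <- list(); cond_lab <- character(); run_lab <- integer()
  for (r in seq_len(geom$n_runs)) {
    er <- design$events[design$events$run == r, ]
    for (cat in cats) {
      ec <- er[er$condition == cat, ]
      cols[[length(cols) + 1L]] <- convolved_regressor(ec, h, dt_s, scan_t,
                                                      run_length_s(geom))
      cond_lab <- c(cond_lab, cat); run_lab <- c(run_lab, r)
    }
  }
  for (r in seq_len(geom$n_runs)) {
    cols[[length(cols) + 1L]] <- rep(1, n_scan)
    cond_lab <- c(cond_lab, NA_character_); run_lab <- c(run_lab, r)
  }
  X <- do.call(cbind, cols)
  cond_cols <- which(!is.na(cond_lab))
  if (any(colSums(abs(X[, cond_cols, drop = FALSE])) == 0)) {
    stop("a condition regressor is identically zero")
  }
  # block the matrix by run: a run's regressors are zero outside that run
  n_runs <- geom$n_runs
  full <- matrix(0, n_scan * n_runs, length(cols))
  for (j in seq_along(cols)) {
    rows <- (run_lab[j] - 1) * n_scan + seq_len(n_scan)
    full[rows, j] <- X[, j]
  }
  structure(list(values = full, condition = cond_lab, run = run_lab,
                 frame_times_s = rep(scan_t, n_runs) +
                   rep((seq_len(n_runs) - 1) * run_length_s(geom), each = n_scan),
                 n_scans_per_run = n_scan, n_runs = n_runs,
                 tr_s = geom$tr_s, condition_names = cats),
            class = "design_matrix")
}

# HRF-convolved boxcar for one run's blocks of a single condition, sampled at
# scan times. Scaled by dt so a sustained block plateaus near the HRF integral
# times the block amplitude.
convolved_regressor <- function(events, h, dt_s, scan_times_s, run_length) {
  n_fine <- ceiling((run_length + 40) / dt_s)
  box <- numeric(n_fine)
  for (i in seq_len(nrow(events))) {
    a <- floor(events$onset[i] / dt_s) + 1
    b <- min(n_fine, ceiling((events$onset[i] + events$duration[i]) / dt_s))
    box[a:b] <- 1
  }
  conv <- convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt_s
  conv[pmin(n_fine, floor(scan_times_s / dt_s) + 1)]
}
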