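#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used throughout the package: the difference of two gamma
#' densities, a positive response peaking around 5 s and a delayed undershoot
#' around 16 s scaled by `undershoot_ratio`. With the default parameters
#' (shape 6 and 16, rate 1/s, ratio 1/6) this is the de-facto standard
#' parameterization of the canonical response; the kernel is truncated at
#' `duration_s` (32 s), by which time it has decayed to numerical zero.
#'
#' @param dt_s Sampling step of the returned kernel, in seconds.
#' @param params A list as returned by [hrf_params()].
#' @return Numeric vector `h` with `h[k]` the kernel value at `(k-1) * dt_s`.
#'   `h(0) = 0` because both gamma shapes exceed 1.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1   # peak near 5 s
#' @export
canonical_hrf <- function(dt_s = 0.1, params = hrf_params()) {
  stopifnot(dt_s > 0)
  p <- params
  if (p$peak_shape <= 0 || p$undershoot_shape <= 0 ||
      p$peak_rate <= 0 || p$undershoot_rate <= 0 || p$undershoot_ratio < 0) {
    stop("HRF shape/rate parameters must be positive")
  }
  t <- seq(0, p$duration_s, by = dt_s)
  dgamma(t, shape = p$peak_shape, rate = p$peak_rate) -
    p$undershoot_ratio * dgamma(t, shape = p$undershoot_shape, rate = p$undershoot_rate)
}

#' HRF parameter set
#'
#' @param peak_shape,undershoot_shape Gamma shape parameters of the response
#'   peak and the undershoot (dimensionless).
#' @param peak_rate,undershoot_rate Gamma rate parameters (1/s).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @param duration_s Kernel support; values beyond this are dropped.
#' @return A named list of class `hrf_params`.
#' @export
hrf_params <- function(peak_shape = 6, undershoot_shape = 16,
                       peak_rate = 1, undershoot_rate = 1,
                       undershoot_ratio = 1 / 6, duration_s = 32) {
  structure(list(peak_shape = peak_shape, undershoot_shape = undershoot_shape,
                 peak_rate = peak_rate, undershoot_rate = undershoot_rate,
                 undershoot_ratio = undershoot_ratio, duration_s = duration_s),
            class = "hrf_params")
}
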