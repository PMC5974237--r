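# Synthetic phosphorescence decay traces.  Excitation cycles of 25 us "on"
# followed by a 275 us "off" window in which the emission decays; photon
# counts in each time bin are Poisson-distributed around
# photon_scale * exp(-t / tau(pO2)) and averaged over the cycles.

#' Generate a synthetic phosphorescence decay trace
#'
#' Samples the 275 us laser-off window at `bin_us` resolution.  The
#' expected count in the bin at time `t` is
#' `photon_scale * exp(-t / tau) + background`, where `tau` follows the
#' Stern-Volmer calibration at the requested pO2.  Counts are summed over
#' `n_cycles` independent Poisson realizations and returned as per-cycle
#' means, mirroring on-line cycle averaging.
#'
#' @param po2_true true oxygen partial pressure, mmHg (>= 0).
#' @param n_cycles number of excitation cycles averaged (>= 1; 3000 in a
#'   typical acquisition).
#' @param photon_scale expected counts per bin per cycle at t = 0
#'   (must be positive).
#' @param background constant background counts per bin per cycle.
#' @param calibration an [sv_calibration()].
#' @param bin_us bin width, microseconds.
#' @param window_us length of the off window, microseconds.
#' @param noiseless if TRUE, return the expected counts with no Poisson
#'   noise (useful for oracle tests).
#' @param seed integer RNG seed.
#' @return object of class `decay_trace`: list with `t_us`, `counts`
#'   (per-cycle means), `n_cycles`, and `truth` (list with `tau_us`,
#'   `po2`, `photon_scale`, `background`).
#' @export
gen_decay <- function(po2_true, n_cycles = 3000L, photon_scale = 1,
                      background = 0.02, calibration = sv_calibration(),
                      bin_us = 1, window_us = 275, noiseless = FALSE,
                      seed = 1L) {
  if (po2_true < 0) stopf("po2_true must be non-negative")
  if (n_cycles < 1) stopf("n_cycles must be >= 1")
  if (photon_scale <= 0) stopf("photon_scale must be positive")
  tau <- po2_to_lifetime(po2_true, calibration)
  t <- seq(bin_us / 2, window_us - bin_us / 2, by = bin_us)
  mu <- photon_scale * exp(-t / tau) + background
  if (noiseless) {
    counts <- mu
  } else {
    set.seed(seed)
    counts <- stats::rpois(length(t), mu * n_cycles) / n_cycles
  }
  structure(list(t_us = t, counts = counts, n_cycles = n_cycles,
                 truth = list(tau_us = tau, po2 = po2_true,
                              photon_scale = photon_scale,
                              background = background)),
            class = "decay_trace")
}
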