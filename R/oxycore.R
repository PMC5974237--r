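# Oximetry core: phosphorescence lifetime fitting, Stern-Volmer calibration,
# Hill saturation, blood oxygen content, oxygen extraction fraction and
# vessel-centerline pO2 extraction.

#' Physiological and physical constants for oxygen transport
#'
#' Bundles the constants used throughout the package.  Defaults are the
#' values customarily used for mouse cortex: oxygen solubility in tissue
#' `alpha` = 1.27e-3 umol O2 / ml / mmHg, oxygen diffusivity `D` = 4000
#' um^2/s, hemoglobin content of red blood cells `c_hb` = 5.3 umol Hb / ml
#' RBC, RBC volume `v_rbc` = 55 um^3 (C57BL/6 mice), and Hill parameters
#' `hill_n` = 2.59, `hill_p50` = 40.2 mmHg for mouse hemoglobin.
#'
#' @param alpha O2 solubility, umol O2 ml^-1 mmHg^-1.
#' @param D O2 diffusivity in tissue, um^2/s.
#' @param c_hb hemoglobin content of RBCs, umol Hb per ml RBC.
#' @param v_rbc RBC volume, um^3.
#' @param hill_n Hill exponent (dimensionless).
#' @param hill_p50 half-saturation pO2, mmHg.
#' @return object of class `oxygen_constants`.
#' @export
#' @examples
#' k <- oxygen_constants()
#' hill_so2(40.2, k)  # 0.5 by definition of P50
oxygen_constants <- function(alpha = 1.27e-3, D = 4000, c_hb = 5.3,
                             v_rbc = 55, hill_n = 2.59, hill_p50 = 40.2) {
  vals <- c(alpha = alpha, D = D, c_hb = c_hb, v_rbc = v_rbc,
            hill_n = hill_n, hill_p50 = hill_p50)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all oxygen constants must be finite and strictly positive")
  structure(as.list(vals), class = "oxygen_constants")
}

#' Stern-Volmer calibration between phosphorescence lifetime and pO2
#'
#' Oxygen quenches the phosphorescence of the probe so that
#' `1/tau = 1/tau0 + kq * pO2`.  The probe calibration constants at 37 C /
#' pH 7.2 are not published for this preparation, so the defaults here are
#' placeholders chosen to be realistic for a PtP-class probe: `tau0` = 60 us
#' (zero-oxygen lifetime) and `kq` such that tau(160 mmHg) is about 20 us.
#' They are configurable and should be replaced by a measured calibration
#' when one is available.
#'
#' @param tau0 zero-oxygen lifetime, microseconds.
#' @param kq quenching constant, mmHg^-1 us^-1.
#' @param po2_max upper end of the validity range, mmHg.
#' @return object of class `sv_calibration`.
#' @export
sv_calibration <- function(tau0 = 60, kq = (1 / 20 - 1 / 60) / 160,
                           po2_max = 400) {
  if (tau0 <= 0 || kq <= 0) stopf("tau0 and kq must be positive")
  structure(list(tau0 = tau0, kq = kq, po2_max = po2_max),
            class = "sv_calibration")
}

#' Forward calibration: lifetime expected at a given pO2
#' @param po2 oxygen partial pressure, mmHg (vectorized).
#' @param calibration an [sv_calibration()].
#' @return lifetime, microseconds.
#' @export
po2_to_lifetime <- function(po2, calibration = sv_calibration()) {
  if (any(po2 < 0)) stopf("po2 must be non-negative")
  1 / (1 / calibration$tau0 + calibration$kq * po2)
}

#' Invert the Stern-Volmer calibration
#'
#' @param tau phosphorescence lifetime, microseconds (vectorized).
#' @param calibration an [sv_calibration()].
#' @return pO2, mmHg (>= 0).
#' @export
lifetime_to_po2 <- function(tau, calibration = sv_calibration()) {
  if (any(tau <= 0)) stopf("tau must be positive")
  if (any(tau > calibration$tau0 * (1 + 1e-9)))
    stopf("tau exceeds tau0 (%g us): unphysical for this calibration",
          calibration$tau0)
  po2 <- (1 / tau - 1 / calibration$tau0) / calibration$kq
  pmax(po2, 0)
}

#' Fit a single-exponential decay to a phosphorescence trace
#'
#' Fits `A * exp(-t / tau) + B` to the averaged photon-count decay by
#' nonlinear least squares.  A constant background `B` is included because
#' in-vivo traces carry a depth-dependent background.  Starting values come
#' from a log-linear regression on the background-subtracted counts.
#'
#' @param trace a `decay_trace` (see [gen_decay()]) or a list with numeric
#'   fields `t_us` (strictly increasing) and `counts` (non-negative).
#' @return list with `tau` (us), `A`, `B`, and `fit_rms` (root mean square
#'   residual in count units).
#' @export
fit_lifetime <- function(trace) {
  t <- trace$t_us
  y <- trace$counts
  if (length(t) < 8L) stopf("need at least 8 time bins, got %d", length(t))
  if (any(diff(t) <= 0)) stopf("time samples must be strictly increasing")
  if (any(y < 0) || sum(y) <= 0) stopf("counts must be non-negative with positive total")
  b0 <- min(y)
  amp <- max(y) - b0
  if (amp <= 0 || stats::sd(y) == 0)
    stopf("no decaying component in trace")
  # log-linear start on the upper part of the decay
  pos <- y - b0 > amp * 0.05
  if (sum(pos) < 4L) pos <- y - b0 > 0
  ylog <- log(pmax(y[pos] - b0, amp * 1e-6))
  sl <- stats::coef(stats::lm(ylog ~ t[pos]))[2]
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else (max(t) - min(t)) / 3
  tau0 <- min(max(tau0, 1), 1000)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ A * exp(-t / tau) + B, data = df,
                 start = list(A = amp, tau = tau0, B = b0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a direct optimizer on the same objective
    obj <- function(p) {
      mu <- p[1] * exp(-t / exp(p[2])) + p[3]
      sum((y - mu)^2)
    }
    op <- stats::optim(c(amp, log(tau0), b0), obj,
                       control = list(maxit = 2000, reltol = 1e-12))
    pars <- c(A = op$par[1], tau = exp(op$par[2]), B = op$par[3])
    rss <- op$value
  } else {
    pars <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
  }
  tau <- unname(pars["tau"])
  if (!is.finite(tau) || tau <= 1 || tau >= 1000)
    stopf("fitted lifetime %.3g us outside the valid (1, 1000) us range", tau)
  if (unname(pars["A"]) <= 0) stopf("no decaying component in trace")
  list(tau = tau, A = unname(pars["A"]), B = unname(pars["B"]),
       fit_rms = sqrt(rss / length(y)))
}

#' Hemoglobin oxygen saturation from pO2 (Hill equation)
#'
#' `SO2 = pO2^n / (pO2^n + P50^n)` with the mouse constants n = 2.59,
#' P50 = 40.2 mmHg by default.
#'
#' @param po2 pO2, mmHg (vectorized, >= 0).
#' @param constants an [oxygen_constants()].
#' @return saturation fraction in `[0, 1)`.
#' @export
hill_so2 <- function(po2, constants = oxygen_constants()) {
  if (any(po2 < 0)) stopf("po2 must be non-negative")
  pn <- po2^constants$hill_n
  pn / (pn + constants$hill_p50^constants$hill_n)
}

#' Oxygen content of blood
#'
#' Dissolved plus hemoglobin-bound oxygen:
#' `[O2] = alpha * pO2 + 4 * Hct * C_Hb * SO2` in umol O2 per ml blood.
#'
#' @param po2 pO2, mmHg.
#' @param so2 saturation fraction in `[0, 1]`.
#' @param hct hematocrit fraction in `[0, 1)`.
#' @param constants an [oxygen_constants()].
#' @return oxygen content, umol O2 / ml blood.
#' @export
o2_content <- function(po2, so2, hct, constants = oxygen_constants()) {
  if (any(hct < 0) || any(hct >= 1)) stopf("hct must be in [0, 1)")
  if (any(so2 < 0) || any(so2 > 1)) stopf("so2 must be in [0, 1]")
  if (any(po2 < 0)) stopf("po2 must be non-negative")
  constants$alpha * po2 + 4 * hct * constants$c_hb * so2
}

#' Oxygen extraction fraction with error propagation
#'
#' `OEF = (SaO2 - SvO2) / SaO2`.  The standard deviation is propagated
#' assuming independent arterial and venous saturations:
#' `sd = sqrt((sv/sa^2)^2 sa_sd^2 + (1/sa)^2 sv_sd^2)`.
#'
#' @param sa_mean,sv_mean mean arteriolar / venular SO2 (fractions).
#' @param sa_sd,sv_sd their standard deviations.
#' @return list with `oef` and `sd`.
#' @export
oef <- function(sa_mean, sv_mean, sa_sd = 0, sv_sd = 0) {
  if (sa_mean <= 0) stopf("arterial saturation must be positive")
  val <- 1 - sv_mean / sa_mean
  sd <- sqrt((sv_mean / sa_mean^2)^2 * sa_sd^2 + (1 / sa_mean)^2 * sv_sd^2)
  list(oef = val, sd = sd)
}

#' Vessel-center pO2 from a transverse line grid
#'
#' Intravascular measurements along a short line across a vessel yield a
#' parabolic pO2 profile; the fitted maximum is taken as the pO2 at the
#' vessel center.  If the fitted parabola opens upward (no interior
#' maximum), the maximum sample is returned and flagged.
#'
#' @param offset_um transverse offsets, micrometres (>= 5 points).
#' @param po2 measured pO2 at each offset, mmHg.
#' @return list with `po2_center`, `offset_at_max`, and `flagged`
#'   (TRUE when the parabolic fit had no interior maximum).
#' @export
vessel_center_po2 <- function(offset_um, po2) {
  if (length(offset_um) < 5L) stopf("need at least 5 points, got %d", length(offset_um))
  if (length(offset_um) != length(po2)) stopf("offset and po2 lengths differ")
  fit <- stats::lm(po2 ~ offset_um + I(offset_um^2))
  a2 <- stats::coef(fit)[3]
  a1 <- stats::coef(fit)[2]
  if (!is.finite(a2) || a2 >= -1e-8) {  # upward-opening or flat: no maximum
    return(list(po2_center = max(po2), offset_at_max = offset_um[which.max(po2)],
                flagged = TRUE))
  }
  xm <- -a1 / (2 * a2)
  xm <- min(max(xm, min(offset_um)), max(offset_um))
  ym <- unname(stats::predict(fit, data.frame(offset_um = xm)))
  list(po2_center = ym, offset_at_max = unname(xm), flagged = FALSE)
}

#' Depth-averaged vessel pO2
#'
#' Unweighted mean of per-depth centerline pO2 values over the first
#' `depth_max` micrometres of cortical depth (default 150 um), matching an
#' acquisition in 30-40 um depth steps.
#'
#' @param depth_um depth of each measurement, micrometres.
#' @param po2 centerline pO2 at each depth, mmHg.
#' @param depth_max depth cutoff, micrometres.
#' @return mean pO2 over depths `<= depth_max`.
#' @export
mean_vessel_po2 <- function(depth_um, po2, depth_max = 150) {
  keep <- depth_um <= depth_max
  if (!any(keep)) stopf("no measurements within the first %g um", depth_max)
  mean(po2[keep])
}
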