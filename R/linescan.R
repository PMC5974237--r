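# Capillary line-scan analysis: diameter, RBC speed, flux, volumetric flow,
# hematocrit and per-unit-length resistance from space-time images.

#' Capillary diameter from a perpendicular space-time image
#'
#' Averages the image along time and fits a Gaussian to the spatial
#' profile; the internal diameter is the full width at half maximum,
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param st a `spacetime_image` with perpendicular orientation.
#' @return diameter in micrometres.
#' @export
estimate_diameter <- function(st) {
  if (!identical(st$orientation, "perpendicular"))
    stopf("diameter estimation needs a perpendicular scan")
  prof <- rowMeans(st$img)
  n <- length(prof)
  if (stats::sd(prof) < 1e-12) stopf("no lumen contrast in image")
  x <- seq_len(n)
  b0 <- min(prof)
  a0 <- max(prof) - b0
  m0 <- x[which.max(prof)]
  w <- pmax(prof - b0, 0)
  s0 <- sqrt(sum(w * (x - m0)^2) / sum(w))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(prof ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
                 start = list(b = b0, a = a0, m = m0, s = max(s0, 1)),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) stopf("no lumen contrast in image (Gaussian fit failed)")
  s <- abs(unname(stats::coef(fit)["s"]))
  fwhm_px <- 2 * sqrt(2 * log(2)) * s
  if (fwhm_px < 2 || fwhm_px > n)
    stopf("fitted lumen width %.1f px outside the valid range [2, %d]", fwhm_px, n)
  fwhm_px * st$dx_um
}

# shear-projection of a space-time image: bin mean intensity by the
# de-skewed coordinate c = pixel - slope * line (slope in px / line).
shear_profile <- function(img, slope) {
  np <- nrow(img)
  nl <- ncol(img)
  ii <- rep(seq_len(np), nl)
  jj <- rep(seq_len(nl), each = np)
  cc <- round(ii - slope * (jj - 1L))
  sums <- rowsum(as.vector(img), cc)
  cnts <- rowsum(rep(1, length(cc)), cc)
  data.frame(c = as.integer(rownames(sums)), mean = sums[, 1] / cnts[, 1],
             n = cnts[, 1])
}

#' RBC speed from a longitudinal space-time image
#'
#' Moving RBCs trace slanted dark streaks; the streak angle is found by a
#' Radon-style search: the image is sheared at candidate angles and the
#' variance of the projected profile is maximized (streaks aligned with the
#' shear give the sharpest projection).  A coarse 2 degree sweep is
#' followed by a 0.25 degree local sweep and parabolic refinement.  The
#' sign of the motion is discarded.
#'
#' @param st a `spacetime_image` with longitudinal orientation.
#' @param theta_max largest streak angle searched, degrees (angle is
#'   measured from the time axis; tan(theta) = pixels advanced per line).
#' @return speed in micrometres per second.
#' @export
estimate_velocity <- function(st, theta_max = 88) {
  if (!identical(st$orientation, "longitudinal"))
    stopf("velocity estimation needs a longitudinal scan")
  img <- st$img
  if (stats::sd(img) < 1e-12) stopf("no dominant streak angle (uniform image)")
  score_img <- function(im, theta) {
    pr <- shear_profile(im, tan(theta * pi / 180))
    keep <- pr$n >= max(pr$n) * 0.5
    if (sum(keep) < 3L) return(0)
    stats::var(pr$mean[keep])
  }
  score <- function(theta) score_img(img, theta)
  coarse <- seq(0, theta_max, by = 2)
  v_coarse <- vapply(coarse, score, numeric(1))
  th0 <- coarse[which.max(v_coarse)]
  # isotropy guard: a deterministic pixel scramble preserves the marginal
  # intensity distribution and the bin-occupancy pattern but destroys any
  # streak structure; genuine streaks beat it by a wide margin
  perm <- order((seq_along(img) * 0.61803398875) %% 1)
  null_img <- matrix(img[perm], nrow(img))
  null_score <- score_img(null_img, th0)
  if (max(v_coarse) <= 0 || max(v_coarse) < 3 * null_score)
    stopf("no dominant streak angle (isotropic image)")
  fine <- seq(max(0, th0 - 2), min(theta_max, th0 + 2), by = 0.25)
  v_fine <- vapply(fine, score, numeric(1))
  k <- which.max(v_fine)
  theta <- fine[k]
  # parabolic refinement on the three points around the maximum
  if (k > 1L && k < length(v_fine)) {
    y1 <- v_fine[k - 1]; y2 <- v_fine[k]; y3 <- v_fine[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) theta <- theta + 0.25 * 0.5 * (y1 - y3) / denom
  }
  slope <- tan(theta * pi / 180)          # px per line
  abs(slope) * st$dx_um / st$line_period_s
}

#' RBC flux from a space-time image
#'
#' Counts the dark shadows and divides by the acquisition time.  The image
#' is collapsed to a one-dimensional intensity profile - along time for
#' perpendicular scans, along the de-skewed streak coordinate for
#' longitudinal scans - and below-threshold runs separated by at least
#' `min_sep` samples are counted.  The threshold is `mean - k * SD` of the
#' profile; when the shadow density is so high that this falls below the
#' darkest profile value (strongly bimodal profile), the midpoint between
#' the dark and bright levels is used instead.
#'
#' @param st a `spacetime_image` of either orientation.
#' @param k threshold depth in SD units (default 1.5).
#' @param min_sep minimum separation between counted shadows, samples.
#' @param speed_um_s RBC speed used to de-skew longitudinal scans; when
#'   NULL it is estimated with [estimate_velocity()].
#' @return flux in shadows per second.
#' @export
count_flux <- function(st, k = 1.5, min_sep = 2L, speed_um_s = NULL) {
  img <- st$img
  rng <- range(img)
  if (diff(rng) < 1e-9) {
    if (mean(img) < 0.1) stopf("saturated or black image")
    return(0)  # uniform bright plasma: no shadows
  }
  duration <- ncol(img) * st$line_period_s
  if (identical(st$orientation, "perpendicular")) {
    # restrict to the lumen rows (above half max of the spatial profile)
    prof <- rowMeans(img)
    lumen <- prof >= min(prof) + 0.5 * (max(prof) - min(prof))
    trace <- colMeans(img[lumen, , drop = FALSE])
  } else {
    v <- speed_um_s %||% tryCatch(estimate_velocity(st), error = function(e) NULL)
    if (is.null(v)) return(0)
    slope <- v * st$line_period_s / st$dx_um
    pr <- shear_profile(img, slope)
    trace <- pr$mean
  }
  thr <- mean(trace) - k * stats::sd(trace)
  if (thr <= min(trace)) thr <- (min(trace) + max(trace)) / 2
  below <- trace < thr
  if (!any(below)) return(0)
  # count below-threshold runs, merging runs separated by < min_sep samples
  r <- rle(below)
  gap_ok <- r$lengths >= min_sep | r$values
  runs <- 0L
  open <- FALSE
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      if (!open) runs <- runs + 1L
      open <- TRUE
    } else if (gap_ok[i]) {
      open <- FALSE
    }
  }
  runs / duration
}

#' Volumetric flow and hematocrit from capillary measurements
#'
#' `flow = speed * pi * (d / 2)^2` and
#' `hct = flux * v_rbc / flow` (RBC volume 55 um^3 for C57BL/6 mice).
#'
#' @param diameter_um lumen diameter, micrometres (> 0).
#' @param speed_um_s RBC speed, micrometres per second (> 0).
#' @param flux_per_s RBC flux, per second (>= 0).
#' @param constants an [oxygen_constants()] (supplies `v_rbc`).
#' @return list with `flow_um3_s`, `hct` and `hct_valid` (FALSE when the
#'   derived hematocrit is >= 1, i.e. non-physiological).
#' @export
derive_flow_hct <- function(diameter_um, speed_um_s, flux_per_s,
                            constants = oxygen_constants()) {
  if (diameter_um <= 0 || speed_um_s <= 0) stopf("diameter and speed must be positive")
  if (flux_per_s < 0) stopf("flux must be non-negative")
  flow <- speed_um_s * pi * (diameter_um / 2)^2
  hct <- flux_per_s * constants$v_rbc / flow
  if (hct >= 1) warning("derived hematocrit >= 1: non-physiological")
  list(flow_um3_s = flow, hct = hct, hct_valid = hct < 1)
}

#' In vitro relative apparent blood viscosity
#'
#' Empirical diameter- and hematocrit-dependent relative viscosity law for
#' blood flowing in narrow glass tubes:
#' `eta_rel = 1 + (eta45 - 1) * ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)`,
#' where `eta45(d)` is the relative viscosity at H = 0.45 and `C(d)` shapes
#' the hematocrit dependence.  Normalized so `eta_rel(d, 0) = 1`
#' (plasma-only limit).
#'
#' @param diameter_um tube diameter, micrometres.
#' @param hct tube hematocrit fraction in `[0, 1)`.
#' @return relative viscosity (dimensionless, >= 1).
#' @export
relative_viscosity <- function(diameter_um, hct) {
  d <- diameter_um
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  shape <- 1 / (1 + 1e-11 * d^12)
  C <- (0.8 + exp(-0.075 * d)) * (shape - 1) + shape
  if (hct == 0) return(1)
  1 + (eta45 - 1) * ((1 - hct)^C - 1) / ((1 - 0.45)^C - 1)
}

#' Capillary resistance per unit length
#'
#' Poiseuille resistance per unit length, `128 eta / (pi d^4)`, with the
#' apparent viscosity from [relative_viscosity()] times the plasma
#' viscosity.  Valid for the capillary range 2-10 um.
#'
#' @param diameter_um lumen diameter, micrometres (2-10).
#' @param hct capillary hematocrit fraction.
#' @param plasma_viscosity_cp plasma viscosity, centipoise.
#' @return resistance per unit length in mmHg s um^-4.
#' @export
capillary_resistance <- function(diameter_um, hct, plasma_viscosity_cp = 1.2) {
  if (diameter_um < 2 || diameter_um > 10)
    stopf("diameter %.2f um outside the capillary range [2, 10] um", diameter_um)
  eta_pa_s <- relative_viscosity(diameter_um, hct) * plasma_viscosity_cp * 1e-3
  r_pa <- 128 * eta_pa_s / (pi * diameter_um^4)  # Pa s / um^4 per um length
  r_pa * 0.0075006  # Pa -> mmHg
}

#' Group summary of capillary measurements
#'
#' Means, standard errors, and the coefficient of variation of RBC speed
#' (spatial heterogeneity, a proxy for capillary transit time
#' heterogeneity).  Sample (n - 1) standard deviations throughout.
#'
#' @param df data frame with columns `diameter_um`, `speed_um_s`,
#'   `flux_per_s`, `flow_um3_s`, `hct` (>= 3 rows).
#' @return list of per-variable `mean` / `sem` plus `speed_cv` and `n`.
#' @export
summarize_capillaries <- function(df) {
  if (nrow(df) < 3L) stopf("need at least 3 capillaries, got %d", nrow(df))
  vars <- intersect(c("diameter_um", "speed_um_s", "flux_per_s",
                      "flow_um3_s", "hct", "resistance"), names(df))
  out <- lapply(vars, function(v) list(mean = mean(df[[v]]), sem = sem(df[[v]])))
  names(out) <- vars
  out$speed_cv <- cv(df$speed_um_s)
  out$n <- nrow(df)
  out
}
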