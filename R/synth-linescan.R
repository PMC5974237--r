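# Synthetic capillary line-scan (kymograph) generator.  Plasma is bright
# (fluorescent dextran), red blood cells are dark shadows.  Perpendicular
# scans cross the capillary, so the time-averaged spatial profile is a
# Gaussian whose FWHM equals the lumen diameter; longitudinal scans run
# along the capillary, so moving RBCs trace slanted dark streaks whose
# slope encodes the speed.

# RBC arrivals as a hard-core renewal process: exponential gaps plus a dead
# time, because RBCs cannot overlap in a single-file capillary.  The mean
# rate equals the requested flux.
rbc_arrivals <- function(flux, dead_time, t_from, t_to, seed) {
  if (flux == 0) return(numeric(0))
  mean_gap <- 1 / flux
  if (mean_gap <= dead_time * 1.05)
    stopf("flux %g /s too high for this speed (dead time %.3g s)", flux, dead_time)
  set.seed(seed)
  span <- t_to - t_from
  n_max <- ceiling(flux * span * 3 + 50)
  gaps <- dead_time + stats::rexp(n_max, rate = 1 / (mean_gap - dead_time))
  tt <- t_from + cumsum(gaps) - gaps[1] * stats::runif(1)
  tt[tt <= t_to]
}

#' Generate a synthetic capillary space-time image
#'
#' @param diameter_um capillary lumen diameter (> 0), micrometres.
#' @param speed_um_s RBC speed (> 0), micrometres per second.
#' @param flux_per_s RBC flux (>= 0), cells per second.
#' @param orientation `"perpendicular"` (scan across the vessel) or
#'   `"longitudinal"` (scan along the vessel).
#' @param duration_s scan duration, seconds (250 ms default, 200 lines).
#' @param n_pixels points per line (100 at 800 Hz by default, ~20 um line).
#' @param dx_um spatial pixel size, micrometres.
#' @param line_period_s time between lines, seconds.
#' @param rbc_length_um length of the dark shadow an RBC casts along the
#'   flow direction, micrometres.
#' @param noise_sd additive Gaussian intensity noise (plasma level is 1).
#' @param seed integer RNG seed.
#' @return object of class `spacetime_image`: list with `img`
#'   (n_pixels x n_lines matrix), `dx_um`, `line_period_s`, `orientation`
#'   and `truth` (diameter/speed/nominal flux plus `n_shadows`,
#'   `flux_realized` = shadows per acquisition time, `flow_um3_s`, `hct`).
#'   `flux_realized` counts the shadows actually rendered in the image
#'   (it can differ from the nominal rate by edge effects, exactly as when
#'   counting streaks in a real kymograph).
#' @export
gen_linescan <- function(diameter_um, speed_um_s, flux_per_s,
                         orientation = c("longitudinal", "perpendicular"),
                         duration_s = 0.25, n_pixels = 100L, dx_um = 0.2,
                         line_period_s = 1 / 800, rbc_length_um = 6,
                         noise_sd = 0, seed = 1L) {
  orientation <- match.arg(orientation)
  if (diameter_um <= 0 || speed_um_s <= 0) stopf("diameter and speed must be positive")
  if (flux_per_s < 0) stopf("flux must be non-negative")
  n_lines <- round(duration_s / line_period_s)
  if (n_lines < 50L) stopf("need at least 50 lines (duration too short)")
  fov <- n_pixels * dx_um
  t_lines <- (seq_len(n_lines) - 1L) * line_period_s
  dead <- rbc_length_um / speed_um_s + 2 * line_period_s + 2 * dx_um / speed_um_s
  flow <- speed_um_s * pi * (diameter_um / 2)^2

  if (orientation == "longitudinal") {
    # streaks: RBC i occupies x in [v (t - t_i) - L, v (t - t_i)]
    t0 <- -(fov + rbc_length_um) / speed_um_s
    tt <- rbc_arrivals(flux_per_s, dead, t0, duration_s, seed)
    img <- matrix(1, n_pixels, n_lines)
    x <- (seq_len(n_pixels) - 0.5) * dx_um
    n_shadows <- 0L
    for (ti in tt) {
      head <- speed_um_s * (t_lines - ti)
      live <- which(head > 0 & head - rbc_length_um < fov)
      drew <- FALSE
      for (j in live) {
        dark <- x <= head[j] & x > head[j] - rbc_length_um
        if (any(dark)) {
          img[dark, j] <- 0.3
          drew <- TRUE
        }
      }
      if (drew) n_shadows <- n_shadows + 1L
    }
    # 1-px Gaussian blur along space (partial-volume softening)
    if (n_pixels >= 5L) {
      kern <- stats::dnorm(-2:2, sd = 1)
      kern <- kern / sum(kern)
      img <- apply(img, 2, function(col) {
        padded <- c(rep(col[1], 2), col, rep(col[length(col)], 2))
        stats::filter(padded, kern, sides = 2)[3:(length(col) + 2)]
      })
    }
  } else {
    # perpendicular: Gaussian lumen profile across the vessel; an RBC
    # passage darkens the lumen for ~L / v seconds
    sigma <- diameter_um / (2 * sqrt(2 * log(2)))
    x <- (seq_len(n_pixels) - 0.5) * dx_um
    center <- fov / 2
    prof <- exp(-(x - center)^2 / (2 * sigma^2))
    tt <- rbc_arrivals(flux_per_s, dead, 0, duration_s, seed)
    amp <- rep(1, n_lines)
    transit <- rbc_length_um / speed_um_s
    for (ti in tt) {
      hit <- t_lines >= ti & t_lines < ti + transit
      amp[hit] <- 0.35
    }
    img <- 0.05 + outer(prof, amp)
    n_shadows <- sum(vapply(tt, function(ti)
      any(t_lines >= ti & t_lines < ti + transit), logical(1)))
  }
  if (noise_sd > 0) {
    set.seed(child_seed(seed, 2L))
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  }
  flux_real <- n_shadows / (n_lines * line_period_s)
  structure(list(img = img, dx_um = dx_um, line_period_s = line_period_s,
                 orientation = orientation,
                 truth = list(diameter_um = diameter_um,
                              speed_um_s = speed_um_s,
                              flux_nominal = flux_per_s,
                              n_shadows = n_shadows,
                              flux_realized = flux_real,
                              flow_um3_s = flow,
                              hct = flux_real * 55 / flow,
                              rbc_length_um = rbc_length_um)),
            class = "spacetime_image")
}
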