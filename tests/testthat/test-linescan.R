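# Line-scan analysis: diameter, velocity, flux, flow/hematocrit,
# resistance and group summaries.

test_that("estimate_diameter recovers the lumen FWHM", {
  st <- gen_linescan(5, 800, 40, "perpendicular", seed = 3)
  expect_equal(estimate_diameter(st), 5, tolerance = 0.2 / 5)  # within 1 px
  # units: doubling dx doubles the reported diameter for the same pixels
  st2 <- st
  st2$dx_um <- st$dx_um * 2
  expect_equal(estimate_diameter(st2), 2 * estimate_diameter(st),
               tolerance = 1e-9)
  # uniform image: no contrast
  flat <- st
  flat$img[] <- 1
  expect_error(estimate_diameter(flat), "no lumen contrast")
  lon <- gen_linescan(5, 800, 40, "longitudinal", seed = 3)
  expect_error(estimate_diameter(lon), "perpendicular")
})

test_that("estimate_velocity recovers streak slopes", {
  # 2.5 px/line at 0.2 um px and 1.25 ms lines -> 400 um/s
  st <- gen_linescan(5, 400, 30, "longitudinal", seed = 5)
  expect_equal(estimate_velocity(st), 400, tolerance = 0.02)
  # noisy fast flow within 5%
  st2 <- gen_linescan(5, 1000, 40, "longitudinal", noise_sd = 0.05, seed = 11)
  expect_equal(estimate_velocity(st2), 1000, tolerance = 0.05)
  # isotropic image rejected
  iso <- st
  set.seed(1)
  iso$img <- matrix(rnorm(length(st$img), 1, 0.1), nrow(st$img))
  expect_error(estimate_velocity(iso), "no dominant streak")
  per <- gen_linescan(5, 400, 30, "perpendicular", seed = 5)
  expect_error(estimate_velocity(per), "longitudinal")
})

test_that("stationary RBCs give vertical streaks and zero velocity", {
  # construct vertical dark bands directly (an RBC parked in the line)
  img <- matrix(1, 100, 200)
  img[40:70, ] <- 0.3
  st <- structure(list(img = img, dx_um = 0.2, line_period_s = 1 / 800,
                       orientation = "longitudinal", truth = NULL),
                  class = "spacetime_image")
  expect_equal(estimate_velocity(st), 0, tolerance = 1e-6)
})

test_that("count_flux counts rendered shadows exactly on noise-free images", {
  for (s in c(2, 7, 13)) {
    lon <- gen_linescan(5, 800, 45, "longitudinal", seed = s)
    expect_equal(count_flux(lon, speed_um_s = 800), lon$truth$flux_realized)
    per <- gen_linescan(5, 800, 45, "perpendicular", seed = s)
    expect_equal(count_flux(per), per$truth$flux_realized)
  }
  # 10 shadows in 0.25 s -> 40 / s by definition
  lon <- gen_linescan(5, 800, 45, "longitudinal", seed = 2)
  expect_equal(lon$truth$flux_realized, lon$truth$n_shadows / 0.25)
  # empty image -> 0
  st0 <- gen_linescan(5, 800, 0, "longitudinal", seed = 1)
  expect_identical(count_flux(st0, speed_um_s = 800), 0)
})

test_that("perpendicular and longitudinal flux estimates agree", {
  ests <- vapply(1:8, function(s) {
    lon <- gen_linescan(5, 1400, 70, "longitudinal", seed = s)
    per <- gen_linescan(5, 1400, 70, "perpendicular", seed = s + 100)
    c(count_flux(lon, speed_um_s = 1400), count_flux(per))
  }, numeric(2))
  expect_lt(abs(mean(ests[1, ]) - mean(ests[2, ])) / mean(ests[1, ]), 0.1)
})

test_that("derive_flow_hct applies the flux * RBC volume / flow identity", {
  res <- derive_flow_hct(5, 1000, 50)
  expect_equal(res$flow_um3_s, 1000 * pi * 6.25)
  expect_equal(res$hct, 50 * 55 / (1000 * pi * 6.25))
  expect_equal(res$hct, 0.140, tolerance = 1e-2)
  expect_identical(derive_flow_hct(5, 1000, 0)$hct, 0)
  # linear in flux at fixed flow
  expect_equal(derive_flow_hct(5, 1000, 80)$hct, 2 * derive_flow_hct(5, 1000, 40)$hct)
  expect_warning(derive_flow_hct(2, 10, 50), "non-physiological")
})

test_that("capillary resistance follows the viscosity law", {
  expect_identical(relative_viscosity(6, 0), 1)
  # d^-4 dominance: resistance drops steeply from 4 to 8 um
  r4 <- capillary_resistance(4, 0.2)
  r8 <- capillary_resistance(8, 0.2)
  expect_gt(r4 / r8, 8)   # more than the 16x of pure d^-4 is not required
  # higher hematocrit, higher resistance
  expect_gt(capillary_resistance(6, 0.30), capillary_resistance(6, 0.14))
  expect_error(capillary_resistance(1, 0.2), "capillary range")
  expect_error(capillary_resistance(12, 0.2), "capillary range")
})

test_that("summarize_capillaries reports CV with sample SD", {
  df <- data.frame(diameter_um = c(5, 5, 5), speed_um_s = c(30, 40, 50),
                   flux_per_s = c(40, 40, 40), flow_um3_s = c(1, 1, 1),
                   hct = c(0.1, 0.1, 0.1))
  s <- summarize_capillaries(df)
  expect_equal(s$speed_cv, 0.25)
  df$speed_um_s <- rep(40, 3)
  expect_equal(summarize_capillaries(df)$speed_cv, 0)
  expect_error(summarize_capillaries(df[1:2, ]), "at least 3")
})

test_that("speed CV is recovered through the velocimetry round trip", {
  # scaled down from the spec-scale cohort (n = 250, 50 seeds) to stay
  # inside the test budget: one cohort of 30 capillaries
  set.seed(20)
  speeds <- 800 * exp(rnorm(30, -0.3^2 / 2, 0.3))
  est <- vapply(seq_along(speeds), function(i) {
    st <- gen_linescan(5, speeds[i], 30, "longitudinal", noise_sd = 0.03,
                       seed = 300 + i)
    estimate_velocity(st)
  }, numeric(1))
  cv_sample <- sd(speeds) / mean(speeds)
  cv_est <- sd(est) / mean(est)
  expect_equal(cv_est, cv_sample, tolerance = 0.1)
})
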