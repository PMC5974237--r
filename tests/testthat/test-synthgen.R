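# Synthetic-cohort generator: presets, decay traces, line scans, tissue
# fields, velocity volumes and angiograms.

test_that("age-group presets carry the published group means", {
  young <- make_cohort_config("young")
  expect_equal(young$arteriolar_po2_mean, 94.7)
  expect_equal(young$venular_po2_mean, 62.9)
  old <- make_cohort_config("old")
  expect_equal(old$tissue_po2_mean, 29.2)
  middle <- make_cohort_config("middle")
  expect_equal(middle$cbf, 2.3)
  expect_error(make_cohort_config("ancient"), "unknown age group")
  # field-by-field override
  cfg <- make_cohort_config("young", cbf = 2.0)
  expect_equal(cfg$cbf, 2.0)
  expect_error(make_cohort_config("young", nonsense = 1), "unknown config field")
  # hypoxic pockets only in the old preset
  expect_length(young$hypoxic_pockets, 0)
  expect_gt(length(old$hypoxic_pockets), 0)
})

test_that("gen_decay: zero quenching gives tau0, noiseless trace is exact", {
  cal <- sv_calibration()
  tr <- gen_decay(0, noiseless = TRUE, background = 0)
  expect_equal(tr$truth$tau_us, cal$tau0)
  expect_equal(tr$counts, exp(-tr$t_us / cal$tau0), tolerance = 1e-12)
})

test_that("gen_decay converges to the expected curve at large cycle counts", {
  tr <- gen_decay(40, n_cycles = 1e5, photon_scale = 2, background = 0, seed = 7)
  mu <- 2 * exp(-tr$t_us / tr$truth$tau_us)
  # law of large numbers: relative error of early (high-count) bins is tiny
  early <- tr$t_us < 50
  expect_lt(max(abs(tr$counts[early] - mu[early]) / mu[early]), 0.02)
})

test_that("gen_decay validates inputs and is deterministic", {
  expect_error(gen_decay(-1), "non-negative")
  expect_error(gen_decay(40, photon_scale = 0), "positive")
  expect_identical(gen_decay(40, seed = 3), gen_decay(40, seed = 3))
})

test_that("gen_linescan renders the stated streak geometry", {
  # flux 0: uniformly bright image
  st0 <- gen_linescan(5, 400, 0, "longitudinal", seed = 1)
  expect_true(all(st0$img == 1))
  expect_identical(st0$truth$n_shadows, 0L)
  expect_error(gen_linescan(0, 400, 10), "positive")
  expect_error(gen_linescan(5, -1, 10), "positive")
  # determinism
  expect_identical(gen_linescan(5, 600, 40, seed = 9),
                   gen_linescan(5, 600, 40, seed = 9))
})

test_that("longitudinal streaks advance speed * period / dx pixels per line", {
  # 400 um/s, 0.2 um px, 1.25 ms lines -> 2.5 px per line
  st <- gen_linescan(5, 400, 20, "longitudinal", seed = 2)
  expect_equal(400 * st$line_period_s / st$dx_um, 2.5)
  # the dark mass center advances by that amount while exactly one full
  # RBC shadow (30 px at 6 um / 0.2 um) is inside the field
  st <- gen_linescan(5, 400, 4, "longitudinal", seed = 2)
  dark <- st$img < 0.6
  single <- which(abs(colSums(dark) - 30) <= 2)
  com <- vapply(single, function(j) mean(which(dark[, j])), numeric(1))
  ok <- diff(single) == 1
  expect_gt(sum(ok), 10)
  # pixel quantization makes single steps alternate 2 and 3; the mean
  # advance is the sub-pixel 2.5
  expect_equal(mean(diff(com)[ok]), 2.5, tolerance = 0.05)
})

test_that("tissue field reproduces the Krogh oracle around one arteriole", {
  g <- vessel_graph(list(penetrating_segment("arteriole", 200, 200)))
  tf <- gen_tissue_field(g, list(oc = 1, po2_art = 90, r_t = 100), n_side = 12)
  pts <- vessel_distances(tf, g)
  r <- pmax(pts$d_art_um, 10)
  expect_equal(pts$po2_mmHg, krogh_po2(r, 1, 90, 10, 100), tolerance = 1e-12)
  # determinism with noise
  tf1 <- gen_tissue_field(g, noise_sd = 2, seed = 5)
  tf2 <- gen_tissue_field(g, noise_sd = 2, seed = 5)
  expect_identical(tf1$points, tf2$points)
})

test_that("tissue field imprints pockets below threshold and validates layout", {
  g <- vessel_graph(list(penetrating_segment("arteriole", 50, 50)))
  pk <- list(list(center_um = c(250, 250, 100), radius_um = 100, floor_mmHg = 2))
  tf <- gen_tissue_field(g, list(oc = 0.5, po2_art = 90, r_t = 100),
                         pockets = pk, n_side = 20)
  d <- sqrt((tf$points$x_um - 250)^2 + (tf$points$y_um - 250)^2 +
              (tf$points$z_um - 100)^2)
  expect_true(all(tf$points$po2_mmHg[d <= 100] < 5))
  expect_error(
    gen_tissue_field(g, pockets = list(list(center_um = c(-50, 0, 0),
                                            radius_um = 10, floor_mmHg = 2))),
    "outside")
  overlapping <- vessel_graph(list(penetrating_segment("arteriole", 100, 100),
                                   penetrating_segment("venule", 105, 100)))
  expect_error(gen_tissue_field(overlapping), "overlapping")
})

test_that("velocity volume: closed-form flow, empty layout, symmetry", {
  lay1 <- list(list(x_um = 200, y_um = 200, radius_um = 15, vmax_mm_s = 8,
                    sign = 1, tilt_deg = 0, azimuth_deg = 0,
                    flow_um3_s = 4000 * pi * 225))
  expect_equal(lay1[[1]]$flow_um3_s, 2.827433e6, tolerance = 1e-6)
  vv <- gen_velocity_volume(lay1, field_um = 400, depth_um = 120)
  # discrete flow integral over a slice matches vmax/2 * pi R^2
  slice_flow <- sum(vv$v[, , 10]) * 1000 * vv$voxel_xy_um^2
  expect_equal(slice_flow, lay1[[1]]$flow_um3_s, tolerance = 0.01)
  # empty layout -> all zeros
  v0 <- gen_velocity_volume(list(), field_um = 200, depth_um = 120)
  expect_true(all(v0$v == 0))
  # mirrored arteriole/venule pair: net signed flow per slice is zero
  lay2 <- list(
    list(x_um = 100, y_um = 100, radius_um = 15, vmax_mm_s = 6, sign = 1,
         tilt_deg = 0, azimuth_deg = 0, flow_um3_s = 3000 * pi * 225),
    list(x_um = 300, y_um = 300, radius_um = 15, vmax_mm_s = 6, sign = -1,
         tilt_deg = 0, azimuth_deg = 0, flow_um3_s = 3000 * pi * 225))
  vv2 <- gen_velocity_volume(lay2, field_um = 400, depth_um = 120)
  expect_lt(abs(sum(vv2$v[, , 15])), 1e-9)
  # undetectably small vessels refused
  tiny <- list(list(x_um = 100, y_um = 100, radius_um = 5, vmax_mm_s = 5,
                    sign = 1, tilt_deg = 0, azimuth_deg = 0, flow_um3_s = 1))
  expect_error(gen_velocity_volume(tiny), "undetectable")
})

test_that("balanced layouts close arterial and venous flow by construction", {
  lay <- make_vessel_layout(3, 4, total_flow_um3_s = 5e6, seed = 8)
  art <- sum(vapply(lay, function(v) if (v$sign > 0) v$flow_um3_s else 0, numeric(1)))
  ven <- sum(vapply(lay, function(v) if (v$sign < 0) v$flow_um3_s else 0, numeric(1)))
  expect_equal(art, 5e6, tolerance = 1e-9)
  expect_equal(art, ven, tolerance = 1e-9)
})

test_that("angiogram stack hits the target capillary density", {
  ang <- gen_angiogram(capillary_density_pct = 3, field_um = 200,
                       depth_um = 100, seed = 4)
  expect_equal(ang$truth$capillary_density_pct, 3, tolerance = 0.2)
  expect_error(gen_angiogram(capillary_density_pct = 25), "non-physiological")
  # density 0: only large vessels
  lay <- list(list(x_um = 100, y_um = 100, radius_um = 15))
  a0 <- gen_angiogram(lay, capillary_density_pct = 0, field_um = 200,
                      depth_um = 60, seed = 1)
  expect_identical(sum(a0$truth$capillary_frac), 0)
  expect_gt(sum(a0$truth$large_frac), 0)
  expect_identical(gen_angiogram(capillary_density_pct = 1, field_um = 120,
                                 depth_um = 60, seed = 2)$intensity,
                   gen_angiogram(capillary_density_pct = 1, field_um = 120,
                                 depth_um = 60, seed = 2)$intensity)
})
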