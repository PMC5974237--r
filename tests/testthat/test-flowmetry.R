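# Velocity-volume flowmetry and angiogram capillary density.

single_vessel <- function(radius = 15, vmax = 8, tilt = 0, sign = 1) {
  list(list(x_um = 200, y_um = 200, radius_um = radius, vmax_mm_s = vmax,
            sign = sign, tilt_deg = tilt, azimuth_deg = 30,
            flow_um3_s = (vmax * 1000 / 2) * pi * radius^2))
}

test_that("detect_vessels_slice finds vessels with the right geometry", {
  vv <- gen_velocity_volume(single_vessel(), field_um = 400, depth_um = 120)
  det <- detect_vessels_slice(vv$v[, , 15], vv$voxel_xy_um)
  expect_identical(nrow(det), 1L)
  expect_equal(det$minor_um, 30, tolerance = vv$voxel_xy_um / 30)
  expect_equal(det$cx_um, 200, tolerance = vv$voxel_xy_um)
  # empty slice
  expect_identical(nrow(detect_vessels_slice(matrix(0, 40, 40), 5)), 0L)
  # mixed-sign touching voxels split by the sign rule
  sl <- matrix(0, 40, 40)
  sl[10:15, 10:15] <- 3
  sl[16:20, 10:15] <- -3
  det2 <- detect_vessels_slice(sl, 5)
  expect_identical(nrow(det2), 2L)
  expect_setequal(det2$sign, c(1, -1))
})

test_that("vessel_metrics respects the projected-flow identity under tilt", {
  vv0 <- gen_velocity_volume(single_vessel(tilt = 0), field_um = 400,
                             depth_um = 120)
  det0 <- detect_vessels_slice(vv0$v[, , 12], vv0$voxel_xy_um)
  m0 <- vessel_metrics(det0)
  # vertical vessel: path velocity equals projected velocity
  expect_equal(m0$path_velocity_mm_s,
               abs(det0$mean_v_mm_s) * det0$major_um / det0$minor_um)
  expect_equal(det0$major_um / det0$minor_um, 1, tolerance = 0.05)
  truth_flow <- single_vessel()[[1]]$flow_um3_s
  expect_equal(m0$flow_um3_s, truth_flow, tolerance = 0.05)
  # tilted vessel: flow unchanged, axis ratio raised
  vv1 <- gen_velocity_volume(single_vessel(tilt = 30), field_um = 400,
                             depth_um = 120)
  det1 <- detect_vessels_slice(vv1$v[, , 12], vv1$voxel_xy_um)
  m1 <- vessel_metrics(det1)
  expect_equal(m1$flow_um3_s, truth_flow, tolerance = 0.05)
  expect_gt(det1$major_um / det1$minor_um, 1.05)
  expect_error(vessel_metrics(data.frame(minor_um = 0, major_um = 1,
                                         mean_v_mm_s = 1, area_um2 = 1,
                                         sign = 1)),
               "degenerate")
})

test_that("depth_profiles conserves flow on closed volumes", {
  lay <- make_vessel_layout(3, 3, total_flow_um3_s = 4e6, seed = 6)
  vv <- gen_velocity_volume(lay, seed = 6)
  prof <- depth_profiles(vv)
  b <- prof$band_50_650
  a <- unname(b["arterial_flow_ml_min"])
  v <- unname(b["venous_flow_ml_min"])
  expect_lt(abs(a - v) / a, 0.02)
  expect_equal(a, 4e6 * 60e-12, tolerance = 0.05)
  # excluded surface band is NA, counts match layout below it
  expect_true(all(is.na(prof$per_depth$arterial_flow_ml_min[
    prof$per_depth$z_um < 50])))
  mid <- prof$per_depth[prof$per_depth$z_um > 100 & prof$per_depth$z_um < 500, ]
  expect_true(all(mid$n_art == 3 & mid$n_ven == 3))
  # single arteriole: venous totals zero
  vv1 <- gen_velocity_volume(single_vessel(), field_um = 400, depth_um = 200)
  p1 <- depth_profiles(vv1)
  expect_identical(unname(p1$band_50_650["venous_flow_ml_min"]), 0)
  # too-shallow volume refused
  shallow <- gen_velocity_volume(list(), field_um = 200, depth_um = 80)
  expect_error(depth_profiles(shallow), "shallower")
})

test_that("estimate_cbf applies the mass normalization", {
  prof <- structure(list(band_50_100 = c(arterial_flow_ml_min = 1.3e-3,
                                         venous_flow_ml_min = 1.3e-3)),
                    class = "flow_depth_profile")
  cbf <- estimate_cbf(prof, area_um2 = 700 * 700)
  expect_equal(cbf, 1.3e-3 / (700 * 700 * 1500 * 1e-12 * 1.05))
  expect_equal(cbf, 1.68, tolerance = 0.005)
  # zero flow, doubling area
  prof0 <- structure(list(band_50_100 = c(arterial_flow_ml_min = 0,
                                          venous_flow_ml_min = 0)),
                     class = "flow_depth_profile")
  expect_identical(estimate_cbf(prof0, 1e6), 0)
  expect_equal(estimate_cbf(prof, 2 * 700 * 700), cbf / 2)
  expect_error(estimate_cbf(structure(list(band_50_100 = NULL),
                                      class = "flow_depth_profile"), 1),
               "50-100")
})

test_that("capillary density from angiograms matches generator truth", {
  # capillaries only
  ang <- gen_angiogram(capillary_density_pct = 3, field_um = 200,
                       depth_um = 100, seed = 4)
  res <- capillary_density_angiogram(ang)
  expect_equal(res$mean_capillary_pct, 3, tolerance = 0.5 / 3)
  # large vessels only: median filter preserves them, density ~ 0
  lay <- list(list(x_um = 100, y_um = 60, radius_um = 15),
              list(x_um = 60, y_um = 140, radius_um = 20))
  ang2 <- gen_angiogram(lay, capillary_density_pct = 0, field_um = 200,
                        depth_um = 60, seed = 2)
  res2 <- capillary_density_angiogram(ang2)
  expect_lt(res2$mean_capillary_pct, 0.5)
  # empty stack -> 0
  empty <- list(intensity = array(0.1, dim = c(40, 40, 10)), voxel_um = 2)
  expect_identical(capillary_density_angiogram(empty)$mean_capillary_pct, 0)
  # oversized kernel refused
  expect_error(capillary_density_angiogram(empty, median_kernel_um = 500),
               "larger than image")
})
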