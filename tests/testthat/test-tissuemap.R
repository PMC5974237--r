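# Tissue pO2 spatial analysis: vessel distances, regions, profiles,
# heterogeneity, hypoxia and pocket detection.

make_graph <- function() {
  vessel_graph(list(penetrating_segment("arteriole", 0, 0, z_max = 400),
                    penetrating_segment("venule", 300, 0, z_max = 400,
                                        radius_um = 12)))
}

test_that("vessel_distances match exact geometry and the resampling oracle", {
  g <- make_graph()
  # 3-4-5 triangle to the vertical arteriole at the origin
  pts <- data.frame(x_um = 30, y_um = 40, z_um = 100)
  d <- vessel_distances(pts, g)
  expect_equal(d$d_art_um, 50)
  # point on the centerline
  on <- vessel_distances(data.frame(x_um = 0, y_um = 0, z_um = 50), g)
  expect_equal(on$d_art_um, 0)
  # missing type -> Inf
  art_only <- vessel_graph(list(penetrating_segment("arteriole", 0, 0)))
  expect_identical(vessel_distances(pts, art_only)$d_ven_um, Inf)
  # random bent polylines vs dense-resampling oracle
  set.seed(4)
  poly <- cbind(cumsum(runif(5, 10, 40)), cumsum(runif(5, -20, 20)),
                seq(0, 200, length.out = 5))
  gg <- vessel_graph(list(list(type = "arteriole", points = poly,
                               radius_um = 8)))
  qs <- matrix(runif(30, -50, 250), ncol = 3)
  got <- vessel_distances(data.frame(x_um = qs[, 1], y_um = qs[, 2],
                                     z_um = qs[, 3]), gg)$d_art_um
  want <- apply(qs, 1, oracle_polyline_dist, poly = poly)
  expect_equal(got, want, tolerance = 0.1)
})

test_that("region classification is an exhaustive partition with arteriole priority", {
  pts <- data.frame(d_art_um = c(50, 150, 150, 99.9),
                    d_ven_um = c(20, 50, 150, 99.9))
  r <- classify_regions(pts)
  expect_equal(as.character(r$region),
               c("near_arteriole", "near_venule", "capillary_bed",
                 "near_arteriole"))
  # partition property on random fields
  set.seed(1)
  pts2 <- data.frame(d_art_um = runif(500, 0, 300), d_ven_um = runif(500, 0, 300))
  r2 <- classify_regions(pts2)
  expect_identical(sum(table(r2$region)), 500L)
  expect_false(any(is.na(r2$region)))
})

test_that("radial profiles sit on the forward-model curve", {
  g <- vessel_graph(list(penetrating_segment("arteriole", 200, 200)))
  tf <- gen_tissue_field(g, list(oc = 1, po2_art = 90, r_t = 100), n_side = 20)
  pts <- vessel_distances(tf, g)
  prof <- radial_profile(pts, "arteriole", bin_width_um = 10)
  # each binned mean within the bin's possible curve range (curve monotone)
  for (i in seq_len(nrow(prof))) {
    lo <- krogh_po2(max(prof$r_mid_um[i] + 5, 10), 1, 90, 10, 100)
    hi <- krogh_po2(max(prof$r_mid_um[i] - 5, 10), 1, 90, 10, 100)
    expect_gte(prof$mean_po2[i], lo - 1e-9)
    expect_lte(prof$mean_po2[i], hi + 1e-9)
  }
  # venular profile exclusion: hot spot near an arteriole is ignored
  pts3 <- data.frame(d_art_um = c(50, 150, 160), d_ven_um = c(30, 35, 36),
                     po2_mmHg = c(95, 40, 41))
  pv <- radial_profile(pts3, "venule", bin_width_um = 10)
  expect_equal(sum(pv$n), 2)
  expect_lt(max(pv$mean_po2), 45)
  # all points beyond max distance -> empty table
  far <- data.frame(d_art_um = 500, d_ven_um = 500, po2_mmHg = 30)
  expect_identical(nrow(radial_profile(far, "arteriole")), 0L)
})

test_that("heterogeneity and hypoxic fraction are the stated statistics", {
  df <- data.frame(po2_mmHg = c(20, 30, 40))
  expect_equal(heterogeneity(df), 10 / 30)
  expect_identical(heterogeneity(data.frame(po2_mmHg = rep(33, 10))), 0)
  expect_error(heterogeneity(data.frame(po2_mmHg = c(1, 2))), "at least 3")
  grid <- data.frame(po2_mmHg = c(rep(2, 10), rep(40, 990)))
  expect_equal(hypoxic_fraction(grid), 0.01)
  expect_identical(hypoxic_fraction(data.frame(po2_mmHg = 5:50)), 0)
  # monotone in threshold, invariant to ordering
  set.seed(2)
  po2 <- runif(400, 0, 60)
  sweeps <- vapply(seq(1, 30, 1), function(th)
    hypoxic_fraction(data.frame(po2_mmHg = po2), th), numeric(1))
  expect_true(all(diff(sweeps) >= 0))
  expect_identical(hypoxic_fraction(data.frame(po2_mmHg = sample(po2))),
                   hypoxic_fraction(data.frame(po2_mmHg = po2)))
})

test_that("detect_pockets equals brute-force union-find on random grids", {
  for (s in 1:5) {
    set.seed(s)
    n <- 400
    pts <- data.frame(x_um = runif(n, 0, 400), y_um = runif(n, 0, 400),
                      z_um = sample(c(60, 100, 140), n, replace = TRUE),
                      po2_mmHg = runif(n, 0, 40))
    res <- detect_pockets(pts, threshold_mmHg = 5, linkage_radius_um = 45)
    hyp <- which(pts$po2_mmHg < 5)
    if (length(hyp) == 0L) {
      expect_length(res$pockets, 0)
      next
    }
    oracle <- oracle_union_find(as.matrix(pts[hyp, 1:3]), 45)
    expect_length(res$pockets, length(unique(oracle)))
    # membership sets agree
    got <- lapply(res$pockets, function(p) sort(p$indices))
    want <- lapply(split(hyp, oracle), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("detect_pockets geometry: discs, separation, emptiness", {
  # single-plane disc of hypoxic points, radius 100 um
  xy <- expand.grid(x_um = seq(0, 400, 10), y_um = seq(0, 400, 10))
  xy$z_um <- 100
  d <- sqrt((xy$x_um - 200)^2 + (xy$y_um - 200)^2)
  xy$po2_mmHg <- ifelse(d <= 100, 2, 35)
  res <- detect_pockets(xy, linkage_radius_um = 15)
  expect_length(res$pockets, 1)
  expect_equal(res$pockets[[1]]$extent_um, 200, tolerance = 0.02)
  # two discs far apart -> two pockets
  d2 <- pmin(sqrt((xy$x_um - 60)^2 + (xy$y_um - 60)^2),
             sqrt((xy$x_um - 340)^2 + (xy$y_um - 340)^2))
  xy$po2_mmHg <- ifelse(d2 <= 40, 2, 35)
  expect_length(detect_pockets(xy, linkage_radius_um = 15)$pockets, 2)
  # nothing hypoxic -> empty result
  xy$po2_mmHg <- 35
  expect_length(detect_pockets(xy, linkage_radius_um = 15)$pockets, 0)
})
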