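# Spatial analysis of 3D tissue pO2 grids: distances to vessels, regional
# classification, radial profiles, heterogeneity, hypoxic fraction and
# micro-pocket detection.

grid_points <- function(grid) {
  if (inherits(grid, "tissue_grid")) grid$points else grid
}

#' Distances from grid points to the nearest arteriole and venule
#'
#' 3D Euclidean point-to-centerline distance, minimized over all segments
#' of each type.  When a vessel type is absent the distance is `Inf`.
#'
#' @param grid a `tissue_grid` or a data frame with `x_um,y_um,z_um`.
#' @param graph a [vessel_graph()].
#' @return the input points with `d_art_um` and `d_ven_um` columns added.
#' @export
vessel_distances <- function(grid, graph) {
  pts <- grid_points(grid)
  P <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
  dist_type <- function(type) {
    segs <- Filter(function(s) s$type == type, graph$segments)
    if (length(segs) == 0L) return(rep(Inf, nrow(P)))
    d <- rep(Inf, nrow(P))
    for (s in segs) d <- pmin(d, dist_to_polyline(P, s$points))
    d
  }
  pts$d_art_um <- dist_type("arteriole")
  pts$d_ven_um <- dist_type("venule")
  pts
}

#' Classify grid points into perivascular regions
#'
#' Three-way exhaustive, disjoint partition with arteriole priority:
#' `near_arteriole` (d_art < cutoff), `near_venule` (d_ven < cutoff and
#' d_art >= cutoff) and `capillary_bed` (both >= cutoff).
#'
#' @param pts data frame with `d_art_um` and `d_ven_um`
#'   (see [vessel_distances()]).
#' @param cutoff_um region cutoff, micrometres (default 100).
#' @return the data frame with a `region` factor column added.
#' @export
classify_regions <- function(pts, cutoff_um = 100) {
  region <- ifelse(pts$d_art_um < cutoff_um, "near_arteriole",
                   ifelse(pts$d_ven_um < cutoff_um, "near_venule",
                          "capillary_bed"))
  pts$region <- factor(region, levels = c("near_arteriole", "near_venule",
                                          "capillary_bed"))
  pts
}

#' Radial pO2 profile around arterioles or venules
#'
#' Bins points by distance to the nearest vessel of the requested type and
#' reports mean pO2, s.e.m. and n per bin.  Venular profiles exclude
#' points within `exclude_art_um` of an arteriole so the dominant
#' arteriolar gradient does not contaminate them.
#'
#' @param pts data frame from [vessel_distances()] with a `po2_mmHg`
#'   column.
#' @param vessel_type `"arteriole"` or `"venule"`.
#' @param bin_width_um bin width, micrometres (default 10).
#' @param max_dist_um largest distance binned.
#' @param exclude_art_um arteriole exclusion radius applied to venular
#'   profiles.
#' @return data frame with `r_mid_um`, `mean_po2`, `sem_po2`, `n`.
#' @export
radial_profile <- function(pts, vessel_type = c("arteriole", "venule"),
                           bin_width_um = 10, max_dist_um = 200,
                           exclude_art_um = 100) {
  vessel_type <- match.arg(vessel_type)
  if (bin_width_um <= 0) stopf("bin_width must be positive")
  d <- if (vessel_type == "arteriole") pts$d_art_um else pts$d_ven_um
  keep <- d <= max_dist_um
  if (vessel_type == "venule") keep <- keep & pts$d_art_um >= exclude_art_um
  d <- d[keep]
  po2 <- pts$po2_mmHg[keep]
  if (length(d) == 0L)
    return(data.frame(r_mid_um = numeric(0), mean_po2 = numeric(0),
                      sem_po2 = numeric(0), n = integer(0)))
  bin <- floor(d / bin_width_um)
  bins <- sort(unique(bin))
  out <- do.call(rbind, lapply(bins, function(b) {
    v <- po2[bin == b]
    data.frame(r_mid_um = (b + 0.5) * bin_width_um, mean_po2 = mean(v),
               sem_po2 = if (length(v) > 1) sem(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Spatial heterogeneity of tissue pO2
#'
#' Coefficient of variation (sample SD / mean) over all grid points.
#'
#' @param grid a `tissue_grid` or data frame with `po2_mmHg`.
#' @return CV (dimensionless).
#' @export
heterogeneity <- function(grid) {
  po2 <- grid_points(grid)$po2_mmHg
  if (length(po2) < 3L) stopf("need at least 3 points")
  m <- mean(po2)
  if (m <= 0) stopf("mean pO2 must be positive")
  stats::sd(po2) / m
}

#' Fraction of hypoxic grid points
#'
#' @param grid a `tissue_grid` or data frame with `po2_mmHg`.
#' @param threshold_mmHg hypoxia threshold (default 5 mmHg, a strong
#'   indicator of pathologically low oxygenation).
#' @return fraction of points with pO2 below the threshold.
#' @export
hypoxic_fraction <- function(grid, threshold_mmHg = 5) {
  if (threshold_mmHg <= 0) stopf("threshold must be positive")
  po2 <- grid_points(grid)$po2_mmHg
  mean(po2 < threshold_mmHg)
}

#' Detect hypoxic micro-pockets
#'
#' Single-linkage connected components of sub-threshold points: two
#' hypoxic points belong to the same pocket when they are within
#' `linkage_radius_um` of each other (directly or through a chain).  Each
#' pocket reports its member points, centroid, mean pO2 and spatial extent
#' (largest pairwise member distance).  Distance-to-arteriole and depth
#' distributions of hypoxic vs all points are returned alongside, when
#' distances are available.
#'
#' @param pts data frame with `x_um,y_um,z_um,po2_mmHg` (and optionally
#'   `d_art_um` for the distance histogram).
#' @param threshold_mmHg hypoxia threshold, mmHg.
#' @param linkage_radius_um linkage radius; should be at least the grid
#'   spacing (default 1.5 x the max in-plane spacing of the data).
#' @return list with `pockets` (list of pockets: `indices`, `n`,
#'   `centroid_um`, `extent_um`, `mean_po2`), `hypoxic_d_art`, `all_d_art`,
#'   `hypoxic_depth`, `all_depth`.
#' @export
detect_pockets <- function(pts, threshold_mmHg = 5, linkage_radius_um = NULL) {
  pts <- grid_points(pts)
  hyp <- which(pts$po2_mmHg < threshold_mmHg)
  if (is.null(linkage_radius_um)) {
    ux <- sort(unique(pts$x_um))
    spacing <- if (length(ux) > 1) max(diff(ux)) else 10
    linkage_radius_um <- 1.5 * spacing
  }
  d_art <- if ("d_art_um" %in% names(pts)) pts$d_art_um else rep(NA_real_, nrow(pts))
  out <- list(pockets = list(),
              hypoxic_d_art = d_art[hyp], all_d_art = d_art,
              hypoxic_depth = pts$z_um[hyp], all_depth = pts$z_um)
  if (length(hyp) == 0L) return(out)
  H <- as.matrix(pts[hyp, c("x_um", "y_um", "z_um")])
  if (length(hyp) == 1L) {
    member <- rep(1L, 1L)
  } else {
    hc <- stats::hclust(stats::dist(H), method = "single")
    member <- stats::cutree(hc, h = linkage_radius_um)
  }
  out$pockets <- lapply(sort(unique(member)), function(m) {
    idx <- hyp[member == m]
    M <- as.matrix(pts[idx, c("x_um", "y_um", "z_um")])
    extent <- if (length(idx) > 1) max(stats::dist(M)) else 0
    list(indices = idx, n = length(idx),
         centroid_um = colMeans(M), extent_um = extent,
         mean_po2 = mean(pts$po2_mmHg[idx]))
  })
  out
}
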