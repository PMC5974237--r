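# Synthetic 3D tissue pO2 grids with typed vessel centerlines and optional
# hypoxic micro-pockets.

#' Construct a typed vessel graph
#'
#' @param segments list of segments; each a list with `type`
#'   (`"arteriole"` or `"venule"`), `points` (m x 3 matrix of centerline
#'   vertices, micrometres) and `radius_um`.
#' @return object of class `vessel_graph`.
#' @export
vessel_graph <- function(segments) {
  for (s in segments) {
    if (!s$type %in% c("arteriole", "venule"))
      stopf("segment type must be arteriole or venule, got '%s'", s$type)
    if (nrow(matrix(s$points, ncol = 3)) < 1L) stopf("degenerate polyline")
    if (s$radius_um <= 0) stopf("vessel radius must be positive")
    if (s$radius_um < 5) stopf("vessels below 10 um diameter are capillaries, not graph segments")
  }
  structure(list(segments = segments), class = "vessel_graph")
}

#' Straight penetrating vessel segment
#'
#' Convenience constructor for a vertical vessel centerline at `(x, y)`
#' running from the surface to `z_max`.
#'
#' @param type `"arteriole"` or `"venule"`.
#' @param x,y in-plane position, micrometres.
#' @param z_max deepest extent, micrometres.
#' @param radius_um vessel radius, micrometres.
#' @return a segment list usable in [vessel_graph()].
#' @export
penetrating_segment <- function(type, x, y, z_max = 300, radius_um = 10) {
  list(type = type, points = rbind(c(x, y, 0), c(x, y, z_max)),
       radius_um = radius_um)
}

#' Generate a synthetic 3D tissue pO2 grid
#'
#' Builds a point grid over stacked imaging planes and evaluates a
#' piecewise forward model: around every arteriole a Krogh cylinder radial
#' profile ([krogh_po2()]); where several arterioles compete the highest
#' profile wins; venules imprint local sinks that pull pO2 toward the
#' venular bed level; hypoxic pockets clamp pO2 to their floor inside the
#' pocket radius with a smooth quadratic recovery outside it (0.02 mmHg/um^2 by default); optional
#' additive Gaussian noise on top (clamped at 0).
#'
#' With a single arteriole, no venules, no pockets and zero noise the
#' sampled points lie exactly on the Krogh curve, which is the oracle used
#' by the profile-recovery tests.
#'
#' @param graph a [vessel_graph()].
#' @param krogh_params list with `oc` (umol ml^-1 min^-1), `po2_art`
#'   (mmHg) and `r_t` (um) applied to every arteriole, or a list of such
#'   lists (one per arteriole).
#' @param pockets list of pockets, each `list(center_um, radius_um,
#'   floor_mmHg)`.
#' @param plane_um in-plane extent (square), micrometres.
#' @param n_side grid points per side per plane (15 x 15 = 225 default).
#' @param z_planes depths of the planes, micrometres.
#' @param venule_sink_mmHg how far venules pull the local field down.
#' @param venule_sigma_um length scale of the venular sink.
#' @param pocket_ramp recovery curvature outside the pocket radius,
#'   mmHg / um^2.
#' @param noise_sd additive Gaussian noise, mmHg.
#' @param seed integer RNG seed.
#' @param constants an [oxygen_constants()].
#' @return object of class `tissue_grid`: list with `points` (data frame
#'   `x_um,y_um,z_um,po2_mmHg`), `graph`, and `truth` (noise-free field,
#'   pockets, Krogh parameters).
#' @export
gen_tissue_field <- function(graph, krogh_params = list(oc = 1, po2_art = 90, r_t = 100),
                             pockets = list(), plane_um = 400, n_side = 15L,
                             z_planes = c(60, 100, 140), venule_sink_mmHg = 12,
                             venule_sigma_um = 40, pocket_ramp = 0.02,
                             noise_sd = 0, seed = 1L,
                             constants = oxygen_constants()) {
  stopifnot(inherits(graph, "vessel_graph"))
  xy <- seq(plane_um / (2 * n_side), plane_um - plane_um / (2 * n_side),
            length.out = n_side)
  pts <- expand.grid(x_um = xy, y_um = xy, z_um = z_planes)
  P <- as.matrix(pts)
  arts <- Filter(function(s) s$type == "arteriole", graph$segments)
  vens <- Filter(function(s) s$type == "venule", graph$segments)
  if (length(arts) == 0L) stopf("need at least one arteriole in the layout")
  # refuse overlapping vessels (centerlines closer than the radii sum)
  segs <- graph$segments
  if (length(segs) > 1L) {
    for (a in seq_len(length(segs) - 1L)) for (b in (a + 1L):length(segs)) {
      pa <- matrix(segs[[a]]$points, ncol = 3)
      res <- apply(pa, 1, function(q) dist_to_polyline(rbind(q), segs[[b]]$points))
      if (min(res) < segs[[a]]$radius_um + segs[[b]]$radius_um)
        stopf("overlapping vessels in layout (segments %d and %d)", a, b)
    }
  }
  if (!is.null(krogh_params$oc)) krogh_params <- rep(list(krogh_params), length(arts))
  if (length(krogh_params) != length(arts))
    stopf("need one Krogh parameter set per arteriole")
  # per-arteriole Krogh profiles; highest local supply wins
  field <- rep(-Inf, nrow(P))
  for (i in seq_along(arts)) {
    kp <- krogh_params[[i]]
    d <- dist_to_polyline(P, arts[[i]]$points)
    r <- pmax(d, arts[[i]]$radius_um)
    field <- pmax(field, krogh_po2(r, kp$oc, kp$po2_art,
                                   arts[[i]]$radius_um, kp$r_t, constants))
  }
  # venular sinks
  for (v in vens) {
    d <- dist_to_polyline(P, v$points)
    field <- field - venule_sink_mmHg * exp(-(d / venule_sigma_um)^2)
  }
  # hypoxic pockets: floor inside the radius, quadratic recovery outside
  for (pk in pockets) {
    ctr <- pk$center_um
    if (any(ctr[1:2] < 0) || any(ctr[1:2] > plane_um))
      stopf("pocket center outside the imaged volume")
    d <- sqrt((P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 + (P[, 3] - ctr[3])^2)
    target <- pk$floor_mmHg + pocket_ramp * pmax(0, d - pk$radius_um)^2
    field <- pmin(field, target)
  }
  truth_field <- field
  if (noise_sd > 0) {
    set.seed(seed)
    field <- field + stats::rnorm(length(field), 0, noise_sd)
  }
  field <- pmax(field, 0)
  pts$po2_mmHg <- field
  structure(list(points = pts, graph = graph,
                 truth = list(po2_true = truth_field, pockets = pockets,
                              krogh_params = krogh_params,
                              noise_sd = noise_sd, seed = seed)),
            class = "tissue_grid")
}
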