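# Synthetic Doppler velocity volumes and angiogram intensity stacks.

#' Build a layout of penetrating vessels
#'
#' Places `n_art` arterioles (positive axial velocity, downward flow) and
#' `n_ven` venules (negative, upward flow) at random non-overlapping
#' positions.  When `total_flow_um3_s` is given, the venular peak
#' velocities are scaled so total venous flow equals total arterial flow
#' (a closed network), and arterial flows are scaled to the requested
#' total.
#'
#' @param n_art,n_ven number of arterioles / venules.
#' @param field_um in-plane field of view (square), micrometres.
#' @param radius_range_um range of vessel radii, micrometres.
#' @param vmax_range_mm_s range of peak axial velocities, mm/s.
#' @param tilt_max_deg largest tilt from vertical, degrees.
#' @param total_flow_um3_s optional target total arterial flow (um^3/s).
#' @param seed integer RNG seed.
#' @return list of vessels (`x_um`, `y_um`, `radius_um`, `vmax_mm_s`,
#'   `sign`, `tilt_deg`, `azimuth_deg`, `flow_um3_s`).
#' @export
make_vessel_layout <- function(n_art = 4L, n_ven = 4L, field_um = 700,
                               radius_range_um = c(12, 25),
                               vmax_range_mm_s = c(3, 10),
                               tilt_max_deg = 0, total_flow_um3_s = NULL,
                               seed = 1L) {
  set.seed(seed)
  n <- n_art + n_ven
  margin <- max(radius_range_um) + 30
  # rejection-sample non-overlapping positions
  xy <- matrix(NA_real_, 0, 2)
  while (nrow(xy) < n) {
    cand <- stats::runif(2, margin, field_um - margin)
    if (nrow(xy) == 0L ||
        min(sqrt((xy[, 1] - cand[1])^2 + (xy[, 2] - cand[2])^2)) > 2.5 * margin / 2)
      xy <- rbind(xy, cand)
  }
  signs <- c(rep(1, n_art), rep(-1, n_ven))
  if (is.null(total_flow_um3_s)) {
    vessels <- lapply(seq_len(n), function(i) {
      r <- stats::runif(1, radius_range_um[1], radius_range_um[2])
      v <- stats::runif(1, vmax_range_mm_s[1], vmax_range_mm_s[2])
      list(x_um = xy[i, 1], y_um = xy[i, 2], radius_um = r, vmax_mm_s = v,
           sign = signs[i], tilt_deg = stats::runif(1, 0, tilt_max_deg),
           azimuth_deg = stats::runif(1, 0, 360),
           flow_um3_s = (v * 1000 / 2) * pi * r^2)
    })
    return(vessels)
  }
  # flow-targeted construction: split the target across vessels, draw a
  # realistic peak velocity and derive the radius from Q = vmax/2 * pi R^2.
  # Keeps peak velocities well above detection thresholds regardless of the
  # requested total.
  share <- function(k) {
    w <- stats::runif(k, 0.6, 1.4)
    total_flow_um3_s * w / sum(w)
  }
  q <- c(share(n_art), share(n_ven))
  vmax <- stats::runif(n, max(vmax_range_mm_s[1], 3), vmax_range_mm_s[2])
  r <- sqrt(2 * q / (pi * vmax * 1000))
  clamp_hi <- r > radius_range_um[2] + 10
  r[clamp_hi] <- radius_range_um[2] + 10
  clamp_lo <- r < radius_range_um[1]
  r[clamp_lo] <- radius_range_um[1]
  clamp <- clamp_hi | clamp_lo
  vmax[clamp] <- 2 * q[clamp] / (pi * r[clamp]^2 * 1000)
  lapply(seq_len(n), function(i) {
    list(x_um = xy[i, 1], y_um = xy[i, 2], radius_um = r[i],
         vmax_mm_s = vmax[i], sign = signs[i],
         tilt_deg = stats::runif(1, 0, tilt_max_deg),
         azimuth_deg = stats::runif(1, 0, 360),
         flow_um3_s = q[i])
  })
}

#' Generate a synthetic en-face axial velocity volume
#'
#' Each penetrating vessel is a tilted cylinder with a parabolic velocity
#' profile along its axis, `v(rho) = vmax (1 - (rho/R)^2)`; the voxel
#' value is the axial (z) component of the velocity, so the volumetric
#' flow through any en-face plane is `(vmax/2) pi R^2` regardless of tilt.
#' Voxels are supersampled 3 x 3 in-plane so discrete flow sums converge
#' to the closed form.
#'
#' @param layout vessel list from [make_vessel_layout()].
#' @param field_um in-plane extent, micrometres.
#' @param depth_um imaged depth, micrometres.
#' @param voxel_xy_um in-plane voxel size, micrometres.
#' @param voxel_z_um slice spacing, micrometres (~3.8 by default).
#' @param noise_sd_mm_s additive Gaussian velocity noise, mm/s.
#' @param seed integer RNG seed.
#' @return object of class `velocity_volume`: list with `v` (3D array,
#'   mm/s, x * y * z), voxel sizes, and `truth` (per-vessel flows um^3/s).
#' @export
gen_velocity_volume <- function(layout, field_um = 700, depth_um = 650,
                                voxel_xy_um = 5, voxel_z_um = 3.8,
                                noise_sd_mm_s = 0, seed = 1L) {
  for (v in layout) {
    if (v$radius_um < 2 * voxel_xy_um)
      stopf("vessel radius %.1f um under 2 voxels: undetectable", v$radius_um)
  }
  nx <- floor(field_um / voxel_xy_um)
  nz <- floor(depth_um / voxel_z_um) + 1L
  zs <- (seq_len(nz) - 1L) * voxel_z_um
  vol <- array(0, dim = c(nx, nx, nz))
  xc <- (seq_len(nx) - 0.5) * voxel_xy_um
  off <- c(-1, 0, 1) * voxel_xy_um / 3  # 3x3 supersampling offsets
  for (v in layout) {
    th <- v$tilt_deg * pi / 180
    az <- v$azimuth_deg * pi / 180
    ux <- sin(th) * cos(az); uy <- sin(th) * sin(az); uz <- cos(th)
    vmax_um <- v$vmax_mm_s * 1000
    halo <- v$radius_um / uz + 2 * voxel_xy_um
    ix <- which(abs(xc - v$x_um) < halo + tan(th) * depth_um)
    iy <- which(abs(xc - v$y_um) < halo + tan(th) * depth_um)
    if (!length(ix) || !length(iy)) next
    for (k in seq_len(nz)) {
      cxk <- v$x_um + ux / uz * zs[k]
      cyk <- v$y_um + uy / uz * zs[k]
      jx <- ix[abs(xc[ix] - cxk) < halo]
      jy <- iy[abs(xc[iy] - cyk) < halo]
      if (!length(jx) || !length(jy)) next
      acc <- matrix(0, length(jx), length(jy))
      for (ox in off) for (oy in off) {
        dx <- xc[jx] + ox - cxk
        dy <- xc[jy] + oy - cyk
        # perpendicular distance^2 of the sample point to the vessel axis
        # P - C is in the slice plane; remove the along-axis component
        dot <- outer(dx * ux, dy * uy, `+`)
        rho2 <- outer(dx^2, dy^2, `+`) - dot^2
        frac <- 1 - rho2 / v$radius_um^2
        frac[frac < 0] <- 0
        acc <- acc + frac
      }
      acc <- acc / 9
      vol[jx, jy, k] <- vol[jx, jy, k] + v$sign * vmax_um * uz * acc / 1000
    }
  }
  if (noise_sd_mm_s > 0) {
    set.seed(seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, noise_sd_mm_s), dim(vol))
  }
  truth <- data.frame(
    sign = vapply(layout, `[[`, numeric(1), "sign"),
    radius_um = vapply(layout, `[[`, numeric(1), "radius_um"),
    vmax_mm_s = vapply(layout, `[[`, numeric(1), "vmax_mm_s"),
    flow_um3_s = vapply(layout, `[[`, numeric(1), "flow_um3_s"))
  structure(list(v = vol, voxel_xy_um = voxel_xy_um, voxel_z_um = voxel_z_um,
                 field_um = field_um, truth = truth),
            class = "velocity_volume")
}

#' Generate a synthetic 3D angiogram intensity stack
#'
#' Large vessels from the layout are rendered as bright vertical tubes;
#' capillaries as randomly oriented thin tubes (diameter < 10 um) added
#' until the requested capillary volume fraction is reached.  Truth
#' records the per-slice capillary and large-vessel volume fractions from
#' the generating masks.
#'
#' @param layout vessel list from [make_vessel_layout()] (may be empty).
#' @param capillary_density_pct target capillary volume fraction, percent
#'   (refused above 20: non-physiological).
#' @param field_um in-plane extent, micrometres.
#' @param depth_um stack depth, micrometres.
#' @param voxel_um isotropic voxel size, micrometres (2 by default).
#' @param cap_diameter_um capillary diameter, micrometres.
#' @param cap_length_um capillary segment length, micrometres.
#' @param noise_sd background intensity noise.
#' @param seed integer RNG seed.
#' @return object of class `angiogram_stack`: list with `intensity` (3D
#'   array in `[0, 1]`), `voxel_um` and `truth` (per-slice fractions).
#' @export
gen_angiogram <- function(layout = list(), capillary_density_pct = 3,
                          field_um = 300, depth_um = 160, voxel_um = 2,
                          cap_diameter_um = 4, cap_length_um = 60,
                          noise_sd = 0.03, seed = 1L) {
  if (capillary_density_pct > 20)
    stopf("capillary density %.1f%% is non-physiological (max 20%%)", capillary_density_pct)
  set.seed(seed)
  nx <- floor(field_um / voxel_um)
  nz <- floor(depth_um / voxel_um)
  big <- array(FALSE, dim = c(nx, nx, nz))
  xc <- (seq_len(nx) - 0.5) * voxel_um
  zc <- (seq_len(nz) - 0.5) * voxel_um
  for (v in layout) {
    d2 <- outer((xc - v$x_um)^2, (xc - v$y_um)^2, `+`)
    disc <- d2 <= v$radius_um^2
    big <- big | array(disc, dim = dim(big))
  }
  cap <- array(FALSE, dim = c(nx, nx, nz))
  target <- capillary_density_pct / 100 * sum(!big)
  r_cap <- cap_diameter_um / 2
  guard <- 0L
  while (sum(cap & !big) < target && guard < 20000L) {
    guard <- guard + 1L
    p0 <- c(stats::runif(2, 0, field_um), stats::runif(1, 0, depth_um))
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    p1 <- p0 + u * cap_length_um
    # rasterize the tube inside its bounding box
    lo <- pmax(pmin(p0, p1) - r_cap - voxel_um, 0)
    hi <- pmin(pmax(p0, p1) + r_cap + voxel_um, c(field_um, field_um, depth_um))
    i0 <- pmax(1L, ceiling(lo / voxel_um)); i1 <- pmin(c(nx, nx, nz), ceiling(hi / voxel_um))
    if (any(i0 > i1)) next
    gx <- xc[i0[1]:i1[1]]; gy <- xc[i0[2]:i1[2]]; gz <- zc[i0[3]:i1[3]]
    G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d <- dist_to_polyline(G, rbind(p0, p1))
    hit <- which(d <= r_cap)
    if (!length(hit)) next
    idx <- cbind(match(G[hit, 1], xc), match(G[hit, 2], xc), match(G[hit, 3], zc))
    cap[idx] <- TRUE
  }
  vasc <- big | cap
  intensity <- array(0.1, dim = dim(vasc))
  intensity[vasc] <- 0.9
  intensity <- intensity + array(stats::rnorm(length(vasc), 0, noise_sd), dim(vasc))
  intensity <- pmin(pmax(intensity, 0), 1)
  slice_frac <- function(m) apply(m, 3, mean)
  structure(list(intensity = intensity, voxel_um = voxel_um,
                 truth = list(capillary_frac = slice_frac(cap & !big),
                              large_frac = slice_frac(big),
                              capillary_density_pct = 100 * sum(cap & !big) / length(cap))),
            class = "angiogram_stack")
}
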