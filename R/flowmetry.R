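# Doppler velocity-volume flowmetry: per-slice vessel detection, vessel
# metrics, depth profiles, CBF estimation, and capillary density from
# angiogram stacks.

#' Detect vessels in one en-face velocity slice
#'
#' Connected components (4-connectivity) of voxels with `|v|` above the
#' threshold and uniform sign; components smaller than `min_voxels` are
#' discarded.  Axis lengths come from the second moments of the component
#' (equivalent-ellipse convention: axis = 4 sqrt(eigenvalue)).
#'
#' @param slice 2D matrix of axial velocity, mm/s (signed).
#' @param voxel_um in-plane voxel size, micrometres.
#' @param v_threshold velocity magnitude threshold, mm/s (default 0.5).
#' @param min_voxels minimum component size (default 4).
#' @return data frame of detections: `cx_um`, `cy_um`, `area_um2`,
#'   `minor_um`, `major_um`, `mean_v_mm_s` (signed mean over the
#'   component), `sign`, `n_voxels`.
#' @export
detect_vessels_slice <- function(slice, voxel_um, v_threshold = 0.5,
                                 min_voxels = 4L) {
  if (v_threshold <= 0) stopf("v_threshold must be positive")
  empty <- data.frame(cx_um = numeric(0), cy_um = numeric(0),
                      area_um2 = numeric(0), minor_um = numeric(0),
                      major_um = numeric(0), mean_v_mm_s = numeric(0),
                      sign = numeric(0), n_voxels = integer(0))
  out <- empty
  for (sgn in c(1, -1)) {
    mask <- (sgn * slice) > v_threshold
    if (!any(mask)) next
    lab <- label_components(mask)
    for (m in seq_len(max(lab))) {
      idx <- which(lab == m)
      if (length(idx) < min_voxels) next
      i <- ((idx - 1L) %% nrow(slice)) + 1L
      j <- ((idx - 1L) %/% nrow(slice)) + 1L
      x <- (i - 0.5) * voxel_um
      y <- (j - 0.5) * voxel_um
      cxx <- stats::var(x) * (length(x) - 1) / length(x)
      cyy <- stats::var(y) * (length(y) - 1) / length(y)
      cxy <- stats::cov(x, y) * (length(x) - 1) / length(x)
      ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
      ev <- pmax(ev, 0) + voxel_um^2 / 12  # voxel footprint correction
      out <- rbind(out, data.frame(
        cx_um = mean(x), cy_um = mean(y),
        area_um2 = length(idx) * voxel_um^2,
        minor_um = 4 * sqrt(ev[2]), major_um = 4 * sqrt(ev[1]),
        mean_v_mm_s = mean(slice[idx]), max_v_mm_s = max(abs(slice[idx])),
        sign = sgn, n_voxels = length(idx)))
    }
  }
  out
}

#' Per-vessel metrics from a detection
#'
#' Diameter is the minor axis; flow is projected area times mean projected
#' (axial) velocity, which equals the flux of blood through the en-face
#' plane for any vessel tilt; velocity along the vessel path is the
#' projected velocity scaled by the major/minor axis ratio.
#'
#' @param det one row of [detect_vessels_slice()] output (or a data frame;
#'   vectorized over rows).
#' @param v_threshold detection threshold (mm/s); when supplied, the flow
#'   is corrected for the sub-threshold rim of the parabolic profile that
#'   the threshold filter clips: for laminar flow the missing flow is
#'   `area * thr^2 / (2 (vmax - thr))`.  NULL disables the correction.
#' @return data frame with `diameter_um`, `path_velocity_mm_s`,
#'   `flow_um3_s` (unsigned), `sign`.
#' @export
vessel_metrics <- function(det, v_threshold = NULL) {
  if (any(det$minor_um <= 0)) stopf("degenerate detection (zero minor axis)")
  flow <- abs(det$mean_v_mm_s) * 1000 * det$area_um2  # um^3 / s
  if (!is.null(v_threshold) && "max_v_mm_s" %in% names(det)) {
    rim <- det$area_um2 * v_threshold^2 /
      (2 * pmax(det$max_v_mm_s - v_threshold, v_threshold)) * 1000
    flow <- flow + rim
  }
  data.frame(diameter_um = det$minor_um,
             path_velocity_mm_s = abs(det$mean_v_mm_s) * det$major_um / det$minor_um,
             flow_um3_s = flow, sign = det$sign)
}

#' Depth profiles of total flow and vessel surface density
#'
#' Runs vessel detection on every en-face slice, sums per-vessel flow by
#' sign, and reports per-depth totals plus band averages.  The top 50 um
#' are excluded (surface pial vessels produce mixed Doppler signs); the
#' standard summaries average 50-650 um (regional means) and 50-100 um
#' (just below the pial surface, used for CBF).
#'
#' @param vv a `velocity_volume`.
#' @param v_threshold,min_voxels passed to [detect_vessels_slice()].
#' @param exclude_top_um excluded surface layer, micrometres.
#' @return object of class `flow_depth_profile`: data frame `per_depth`
#'   (`z_um`, `arterial_flow_ml_min`, `venous_flow_ml_min`,
#'   `surface_density`, `n_art`, `n_ven`) plus band summaries
#'   `band_50_650` and `band_50_100` (means over those depths).
#' @export
depth_profiles <- function(vv, v_threshold = 0.5, min_voxels = 4L,
                           exclude_top_um = 50) {
  nz <- dim(vv$v)[3]
  zs <- (seq_len(nz) - 1L) * vv$voxel_z_um
  if (max(zs) < 100) stopf("volume shallower than 100 um")
  um3s_to_mlmin <- 60 * 1e-12
  rows <- lapply(seq_len(nz), function(k) {
    if (zs[k] < exclude_top_um)
      return(data.frame(z_um = zs[k], arterial_flow_ml_min = NA_real_,
                        venous_flow_ml_min = NA_real_, surface_density = NA_real_,
                        n_art = NA_integer_, n_ven = NA_integer_))
    det <- detect_vessels_slice(vv$v[, , k], vv$voxel_xy_um, v_threshold,
                                min_voxels)
    if (nrow(det) == 0L)
      return(data.frame(z_um = zs[k], arterial_flow_ml_min = 0,
                        venous_flow_ml_min = 0, surface_density = 0,
                        n_art = 0L, n_ven = 0L))
    met <- vessel_metrics(det, v_threshold = v_threshold)
    area_field <- (dim(vv$v)[1] * vv$voxel_xy_um) * (dim(vv$v)[2] * vv$voxel_xy_um)
    data.frame(
      z_um = zs[k],
      arterial_flow_ml_min = sum(met$flow_um3_s[met$sign > 0]) * um3s_to_mlmin,
      venous_flow_ml_min = sum(met$flow_um3_s[met$sign < 0]) * um3s_to_mlmin,
      surface_density = sum(det$area_um2) / area_field,
      n_art = sum(det$sign > 0), n_ven = sum(det$sign < 0))
  })
  per_depth <- do.call(rbind, rows)
  band <- function(lo, hi) {
    sel <- per_depth$z_um >= lo & per_depth$z_um <= hi &
      !is.na(per_depth$arterial_flow_ml_min)
    if (!any(sel)) return(NULL)
    colMeans(per_depth[sel, c("arterial_flow_ml_min", "venous_flow_ml_min",
                              "surface_density")])
  }
  structure(list(per_depth = per_depth,
                 band_50_650 = band(exclude_top_um, 650),
                 band_50_100 = band(exclude_top_um, 100)),
            class = "flow_depth_profile")
}

#' Regional cerebral blood flow from a flow depth profile
#'
#' Mean of arterial and venous total flow over the 50-100 um band,
#' normalized by the cortical mass under the scanned area:
#' `CBF = flow / (area * thickness * density)` in ml/g/min.
#'
#' @param profile a `flow_depth_profile`.
#' @param area_um2 scanned cortical surface area, um^2.
#' @param thickness_um assumed cortical thickness (1500 um).
#' @param density_g_per_ml brain density (1.05 g/ml).
#' @return CBF, ml/g/min.
#' @export
estimate_cbf <- function(profile, area_um2, thickness_um = 1500,
                         density_g_per_ml = 1.05) {
  if (area_um2 <= 0) stopf("area must be positive")
  b <- profile$band_50_100
  if (is.null(b)) stopf("no slices in the 50-100 um band")
  flow_ml_min <- mean(c(b["arterial_flow_ml_min"], b["venous_flow_ml_min"]))
  mass_g <- area_um2 * thickness_um * 1e-12 * density_g_per_ml
  unname(flow_ml_min / mass_g)
}

#' Capillary density versus depth from an angiogram stack
#'
#' Each slice is binarized; the capillary fraction is the total vascular
#' fraction minus the large-vessel fraction obtained by applying a median
#' (majority) filter sized to erase structures thinner than ~10 um.
#'
#' @param stack an `angiogram_stack` (or list with `intensity`, `voxel_um`).
#' @param bin_threshold binarization threshold on intensity.
#' @param median_kernel_um median filter kernel size, micrometres
#'   (default 11; must cover at least 3 voxels).
#' @param depth_band_um band over which the summary mean is taken
#'   (default 0-150 um).
#' @return list with `per_depth` (data frame `z_um`, `total_pct`,
#'   `large_pct`, `capillary_pct`) and `mean_capillary_pct` over the band.
#' @export
capillary_density_angiogram <- function(stack, bin_threshold = 0.5,
                                        median_kernel_um = 11,
                                        depth_band_um = c(0, 150)) {
  vox <- stack$voxel_um
  k <- max(3L, round(median_kernel_um / vox))
  if (k %% 2L == 0L) k <- k + 1L
  nz <- dim(stack$intensity)[3]
  zs <- (seq_len(nz) - 0.5) * vox
  rows <- lapply(seq_len(nz), function(i) {
    bw <- stack$intensity[, , i] > bin_threshold
    total <- mean(bw)
    large <- mean(binary_median(bw, k))
    data.frame(z_um = zs[i], total_pct = 100 * total, large_pct = 100 * large,
               capillary_pct = 100 * max(total - large, 0))
  })
  per_depth <- do.call(rbind, rows)
  sel <- per_depth$z_um >= depth_band_um[1] & per_depth$z_um <= depth_band_um[2]
  list(per_depth = per_depth,
       mean_capillary_pct = mean(per_depth$capillary_pct[sel]))
}
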