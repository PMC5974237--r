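# Integrative oxygen budget: CMRO2 by Fick's principle, per-arteriole O2
# delivery from the longitudinal oxygen-flow gradient, parallel-tube
# capillary counts, and the arteriolar share of oxygen supply.

#' Cerebral metabolic rate of oxygen consumption (Fick's principle)
#'
#' `CMRO2 = CBF * ([O2]a - [O2]v)` in umol O2 / g / min.
#'
#' @param cbf cerebral blood flow, ml/g/min (>= 0).
#' @param o2_content_a,o2_content_v arterial / venous oxygen content,
#'   umol O2 / ml blood (see [o2_content()]).
#' @return CMRO2, umol O2 / g / min.
#' @export
cmro2 <- function(cbf, o2_content_a, o2_content_v) {
  if (cbf < 0) stopf("cbf must be non-negative")
  if (o2_content_a < o2_content_v)
    warning("arterial O2 content below venous: unphysical inputs")
  cbf * (o2_content_a - o2_content_v)
}

#' Oxygen delivery to tissue by one arteriole
#'
#' Mass balance along the diving arteriole: the oxygen given off per unit
#' length is the longitudinal gradient of the oxygen flow,
#' `O2_delivery = -Q * d[O2]/dz`, with
#' `d[O2]/dz = alpha * dpO2/dz + 4 * Hct * C_Hb * dSO2/dz`.
#' Both slopes are least-squares lines over the first 0-150 um of depth.
#' The dissolved term is ~2% of the bound term and can be dropped with
#' `include_dissolved = FALSE`.
#'
#' @param depth_um depths of the measurements, micrometres.
#' @param po2 pO2 at each depth, mmHg.
#' @param so2 SO2 at each depth (fractions); computed from `po2` via
#'   [hill_so2()] when NULL.
#' @param q_ml_min mean blood flow in the arteriole, ml/min.
#' @param hct hematocrit fraction.
#' @param constants an [oxygen_constants()].
#' @param depth_max depth cutoff for the slope fit, micrometres.
#' @param include_dissolved include the dissolved-oxygen slope term.
#' @return O2 delivery per unit vessel length, umol O2 / min / um.
#' @export
arteriole_o2_delivery <- function(depth_um, po2, so2 = NULL, q_ml_min,
                                  hct, constants = oxygen_constants(),
                                  depth_max = 150, include_dissolved = TRUE) {
  if (missing(q_ml_min) || is.null(q_ml_min)) stopf("vessel flow Q is required")
  keep <- depth_um <= depth_max
  if (sum(keep) < 3L) stopf("need at least 3 depth samples within 0-%g um", depth_max)
  z <- depth_um[keep]
  if (is.null(so2)) so2 <- hill_so2(po2, constants)
  dso2_dz <- unname(stats::coef(stats::lm(so2[keep] ~ z))[2])
  dpo2_dz <- unname(stats::coef(stats::lm(po2[keep] ~ z))[2])
  slope <- 4 * hct * constants$c_hb * dso2_dz
  if (include_dissolved) slope <- slope + constants$alpha * dpo2_dz
  -q_ml_min * slope
}

#' Capillary count from the parallel-tube network model
#'
#' The capillary bed is idealized as N identical parallel tubes connecting
#' one arteriole to one venule; mass conservation gives
#' `N = regional volumetric flow / mean capillary flow`.
#'
#' @param cbf_volumetric_um3_s total volumetric inflow to the region, um^3/s.
#' @param mean_capillary_flow_um3_s mean single-capillary flow, um^3/s (> 0).
#' @param field_area_um2 optional field area for the linear density.
#' @return list with `n_capillaries` and (if area given)
#'   `density_per_mm2`.
#' @export
capillary_count_parallel_model <- function(cbf_volumetric_um3_s,
                                           mean_capillary_flow_um3_s,
                                           field_area_um2 = NULL) {
  if (mean_capillary_flow_um3_s <= 0) stopf("mean capillary flow must be positive")
  n <- cbf_volumetric_um3_s / mean_capillary_flow_um3_s
  out <- list(n_capillaries = n)
  if (!is.null(field_area_um2))
    out$density_per_mm2 <- n / (field_area_um2 * 1e-6)
  out
}

#' Arteriolar share of tissue oxygen supply
#'
#' The net consumption OC recovered by the Krogh fit is the part of CMRO2
#' not covered by capillary supply, i.e. the part the arteriole itself
#' provides to its tissue cylinder.  The arteriolar supply fraction is
#' therefore `OC / CMRO2` (both per unit tissue volume; CMRO2 in
#' umol/g/min is converted using the brain density).
#'
#' @param oc net oxygen consumption from the Krogh fit,
#'   umol O2 ml^-1 min^-1.
#' @param cmro2 CMRO2, umol O2 g^-1 min^-1.
#' @param density_g_per_ml brain density (1.05 g/ml).
#' @return list with `fraction` (clamped to `[0, 1]`),
#'   `capillary_supply` (umol ml^-1 min^-1) and `clamped`.
#' @export
arteriolar_supply_fraction <- function(oc, cmro2, density_g_per_ml = 1.05) {
  if (cmro2 <= 0) stopf("cmro2 must be positive")
  cmro2_ml <- cmro2 * density_g_per_ml  # per g -> per ml tissue
  frac <- oc / cmro2_ml
  clamped <- FALSE
  if (frac > 1) {
    warning("OC exceeds CMRO2: fraction clamped to 1")
    frac <- 1
    clamped <- TRUE
  }
  if (frac < 0) frac <- 0
  list(fraction = frac, capillary_supply = cmro2_ml - oc, clamped = clamped)
}

#' Generate a Fick-consistent synthetic cohort
#'
#' A "coupled" generation mode in which a single CMRO2 truth drives every
#' modality: CBF is taken from the group preset, the venular pO2 is solved
#' so that `CBF * ([O2]a - [O2]v)` equals the chosen CMRO2, the velocity
#' volume is scaled to carry exactly the CBF, and the periarteriolar
#' tissue field uses an OC equal to the chosen arteriolar share of CMRO2.
#' Downstream, [cmro2()] and [arteriolar_supply_fraction()] must recover
#' the generator truths.
#'
#' @param config a [make_cohort_config()] configuration.
#' @param cmro2_true CMRO2 truth, umol O2 / g / min.
#' @param arteriolar_share true arteriolar supply fraction (0-1).
#' @param field_um,depth_um velocity volume geometry, micrometres.
#' @param constants an [oxygen_constants()].
#' @return list with `po2_art`, `po2_ven` (solved), `volume`
#'   (a `velocity_volume` carrying the preset CBF), `oc_true`
#'   (umol ml^-1 min^-1), `tissue` (a periarteriolar `tissue_grid`
#'   generated with `oc_true`) plus `tissue_graph`, `area_um2`, and
#'   `truth`.
#' @export
gen_coupled_cohort <- function(config, cmro2_true = 2.0,
                               arteriolar_share = 0.25, field_um = 700,
                               depth_um = 650,
                               constants = oxygen_constants()) {
  stopifnot(inherits(config, "sim_config"))
  hct <- config$systemic_hct
  po2_a <- config$arteriolar_po2_mean
  ca <- o2_content(po2_a, hill_so2(po2_a, constants), hct, constants)
  need_cv <- ca - cmro2_true / config$cbf
  if (need_cv <= 0) stopf("CMRO2 too high for this CBF and arterial content")
  f <- function(p) o2_content(p, hill_so2(p, constants), hct, constants) - need_cv
  po2_v <- stats::uniroot(f, c(1e-6, po2_a))$root
  # velocity volume carrying exactly the preset CBF
  area_um2 <- field_um^2
  mass_g <- area_um2 * 1500 * 1e-12 * 1.05
  total_flow_ml_min <- config$cbf * mass_g
  total_flow_um3_s <- total_flow_ml_min / (60 * 1e-12)
  layout <- make_vessel_layout(n_art = 3L, n_ven = 3L, field_um = field_um,
                               total_flow_um3_s = total_flow_um3_s,
                               seed = child_seed(config$rng_seed, 11L))
  vol <- gen_velocity_volume(layout, field_um = field_um, depth_um = depth_um,
                             seed = child_seed(config$rng_seed, 12L))
  oc_true <- arteriolar_share * cmro2_true * 1.05  # per ml tissue
  # periarteriolar tissue field consuming exactly the arteriolar share
  graph <- vessel_graph(list(penetrating_segment("arteriole", 200, 200)))
  tissue <- gen_tissue_field(graph, list(oc = oc_true, po2_art = po2_a,
                                         r_t = 130),
                             noise_sd = 1, n_side = 20L,
                             seed = child_seed(config$rng_seed, 13L),
                             constants = constants)
  list(po2_art = po2_a, po2_ven = po2_v, volume = vol, oc_true = oc_true,
       tissue = tissue, tissue_graph = graph, area_um2 = area_um2,
       truth = list(cmro2 = cmro2_true, arteriolar_share = arteriolar_share,
                    cbf = config$cbf, hct = hct,
                    total_flow_ml_min = total_flow_ml_min))
}
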