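# End-to-end cohort orchestration: simulate every modality for each age
# group at desk scale, run all analysis stages, assemble a report with
# group statistics, and write it to disk.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", stage, conditionMessage(e)))
}

# solve the per-group Krogh consumption so the far-field plateau matches
# the group tissue pO2 (slightly above it: venular sinks pull the mean down)
solve_group_oc <- function(po2_art, tissue_target, r_art = 10, r_t = 130,
                           constants = oxygen_constants()) {
  drop_per_oc <- -krogh_bracket(r_t, r_art, r_t) / (60 * 4 * constants$alpha * constants$D)
  (po2_art - tissue_target) / drop_per_oc
}

simulate_group <- function(config, n_vessels = 8L, n_capillaries = 12L,
                           n_cycles = 3000L, constants = oxygen_constants()) {
  seed <- config$rng_seed
  depths <- c(30, 70, 110, 150)
  z_slope <- -0.08  # mmHg per um of depth along diving vessels

  ## --- vascular pO2 stage -------------------------------------------------
  vascular <- with_stage("vascular", {
    rows <- list()
    for (type in c("arteriole", "venule")) {
      mu <- if (type == "arteriole") config$arteriolar_po2_mean else config$venular_po2_mean
      sem0 <- if (type == "arteriole") config$arteriolar_po2_sem else config$venular_po2_sem
      sd_vessel <- sem0 * sqrt(21)  # per-vessel spread implied by the s.e.m.
      set.seed(child_seed(seed, if (type == "arteriole") 1L else 2L))
      truths <- pmax(stats::rnorm(n_vessels, mu, sd_vessel), 10)
      for (i in seq_len(n_vessels)) {
        po2_d <- numeric(length(depths))
        for (k in seq_along(depths)) {
          true_zd <- max(truths[i] + z_slope * depths[k], 5)
          tr <- gen_decay(true_zd, n_cycles = n_cycles,
                          seed = child_seed(seed, 100L + i * 10L + k +
                                              1000L * (type == "venule")))
          po2_fit <- lifetime_to_po2(fit_lifetime(tr)$tau)
          # transverse line grid: parabola peaking at the fitted value
          off <- seq(-6, 6, length.out = 11)
          set.seed(child_seed(seed, 500L + i * 10L + k))
          par_po2 <- po2_fit * (1 - 0.25 * (off / 6)^2) + stats::rnorm(11, 0, 0.8)
          po2_d[k] <- vessel_center_po2(off, par_po2)$po2_center
        }
        rows[[length(rows) + 1L]] <- data.frame(
          type = type, vessel = i,
          po2_mmHg = mean_vessel_po2(depths, po2_d),
          so2 = mean(hill_so2(pmax(po2_d, 0), constants)),
          stringsAsFactors = FALSE)
      }
    }
    per_vessel <- do.call(rbind, rows)
    sa <- per_vessel$so2[per_vessel$type == "arteriole"]
    sv <- per_vessel$so2[per_vessel$type == "venule"]
    list(per_vessel = per_vessel,
         po2_art_mean = mean(per_vessel$po2_mmHg[per_vessel$type == "arteriole"]),
         po2_ven_mean = mean(per_vessel$po2_mmHg[per_vessel$type == "venule"]),
         so2_art = mean(sa), so2_ven = mean(sv),
         oef = oef(mean(sa), mean(sv), stats::sd(sa), stats::sd(sv)))
  })

  ## --- tissue pO2 stage ---------------------------------------------------
  tissue <- with_stage("tissue", {
    graph <- vessel_graph(list(
      penetrating_segment("arteriole", 100, 100),
      penetrating_segment("arteriole", 300, 300),
      penetrating_segment("venule", 100, 300, radius_um = 12),
      penetrating_segment("venule", 300, 100, radius_um = 12)))
    oc_true <- solve_group_oc(config$arteriolar_po2_mean,
                              config$tissue_po2_mean, constants = constants)
    kp <- list(oc = oc_true, po2_art = config$arteriolar_po2_mean, r_t = 130)
    tg <- gen_tissue_field(graph, kp, pockets = config$hypoxic_pockets,
                           noise_sd = 1.5, seed = child_seed(seed, 3L),
                           constants = constants)
    pts <- classify_regions(vessel_distances(tg, graph))
    pts$po2_mmHg <- tg$points$po2_mmHg
    regional <- stats::aggregate(po2_mmHg ~ region, pts, mean)
    pockets <- detect_pockets(pts)
    # Krogh fits around each arteriole (points nearest to it, away from venules)
    arts <- which(vapply(graph$segments, function(s) s$type == "arteriole", logical(1)))
    fits <- list()
    for (a in arts) {
      d_a <- dist_to_polyline(as.matrix(pts[, c("x_um", "y_um", "z_um")]),
                              graph$segments[[a]]$points)
      sel <- d_a <= 140 & abs(d_a - pts$d_art_um) < 1e-9 & pts$d_ven_um > 120
      if (sum(sel) >= 6L && diff(range(d_a[sel])) >= 60) {
        fits[[length(fits) + 1L]] <-
          fit_krogh(pmax(d_a[sel], 10), pts$po2_mmHg[sel], r_art = 10,
                    constants = constants)
      }
    }
    list(points = pts, mean_po2 = mean(pts$po2_mmHg), cv = heterogeneity(pts),
         hypoxic_fraction = hypoxic_fraction(pts),
         n_pockets = length(pockets$pockets),
         pocket_extents_um = vapply(pockets$pockets, `[[`, numeric(1), "extent_um"),
         regional = regional,
         profile_art = radial_profile(pts, "arteriole"),
         profile_ven = radial_profile(pts, "venule"),
         krogh_fits = fits, oc_true = oc_true)
  })

  ## --- capillary line-scan stage ------------------------------------------
  capillaries <- with_stage("capillary", {
    cp <- config$capillary
    set.seed(child_seed(seed, 4L))
    cvs <- cp$speed_cv
    speeds <- cp$speed_um_s * exp(stats::rnorm(n_capillaries, -cvs^2 / 2, cvs))
    diams <- pmin(pmax(stats::rnorm(n_capillaries, cp$diameter_um, 0.4), 3), 8)
    fluxes <- cp$flux_per_s * speeds / cp$speed_um_s  # constant linear density
    rows <- lapply(seq_len(n_capillaries), function(i) {
      lon <- gen_linescan(diams[i], speeds[i], fluxes[i], "longitudinal",
                          noise_sd = 0.03, seed = child_seed(seed, 600L + i))
      per <- gen_linescan(diams[i], speeds[i], fluxes[i], "perpendicular",
                          noise_sd = 0.03, seed = child_seed(seed, 700L + i))
      v_est <- estimate_velocity(lon)
      d_est <- estimate_diameter(per)
      fx <- mean(c(count_flux(lon, speed_um_s = v_est), count_flux(per)))
      fh <- derive_flow_hct(d_est, v_est, fx)
      data.frame(diameter_um = d_est, speed_um_s = v_est, flux_per_s = fx,
                 flow_um3_s = fh$flow_um3_s, hct = fh$hct,
                 resistance = capillary_resistance(min(max(d_est, 2), 10),
                                                   min(fh$hct, 0.9)))
    })
    df <- do.call(rbind, rows)
    list(table = df, summary = summarize_capillaries(df),
         truth = data.frame(diameter_um = diams, speed_um_s = speeds,
                            flux_per_s = fluxes))
  })

  ## --- flow / budget stage ------------------------------------------------
  budget <- with_stage("flow_budget", {
    hct <- config$systemic_hct
    ca <- o2_content(config$arteriolar_po2_mean,
                     hill_so2(config$arteriolar_po2_mean, constants), hct, constants)
    cvn <- o2_content(config$venular_po2_mean,
                      hill_so2(config$venular_po2_mean, constants), hct, constants)
    cmro2_true <- config$cbf * (ca - cvn)
    coh <- gen_coupled_cohort(config, cmro2_true = cmro2_true,
                              arteriolar_share = 0.25, constants = constants)
    prof <- depth_profiles(coh$volume)
    cbf_est <- estimate_cbf(prof, coh$area_um2)
    ca_m <- o2_content(vascular$po2_art_mean, vascular$so2_art, hct, constants)
    cv_m <- o2_content(vascular$po2_ven_mean, vascular$so2_ven, hct, constants)
    cmro2_est <- cmro2(cbf_est, ca_m, cv_m)
    # per-arteriole O2 delivery from the measured depth profile slope
    q_art <- mean(coh$volume$truth$flow_um3_s[coh$volume$truth$sign > 0]) * 60e-12
    po2_z <- config$arteriolar_po2_mean + z_slope * depths
    deliv <- arteriole_o2_delivery(depths, po2_z, q_ml_min = q_art, hct = hct,
                                   constants = constants)
    oc_meas <- if (length(tissue$krogh_fits) >= 3L) {
      oc_statistics(tissue$krogh_fits)$oc$mean
    } else if (length(tissue$krogh_fits) > 0L) {
      mean(vapply(tissue$krogh_fits, `[[`, numeric(1), "oc"))
    } else tissue$oc_true
    asf <- arteriolar_supply_fraction(oc_meas, cmro2_est)
    flow_band <- prof$band_50_100
    total_q_um3_s <- mean(flow_band[c("arterial_flow_ml_min",
                                      "venous_flow_ml_min")]) / 60e-12
    par_model <- capillary_count_parallel_model(
      total_q_um3_s, mean(capillaries$table$flow_um3_s), coh$area_um2)
    list(cbf_est = cbf_est, cmro2_est = cmro2_est, cmro2_true = cmro2_true,
         oef = vascular$oef$oef, delivery_umol_min_um = deliv,
         oc_mean = oc_meas, supply_fraction = asf$fraction,
         n_capillaries_model = par_model$n_capillaries,
         capillary_density_per_mm2 = par_model$density_per_mm2,
         depth_profile = prof$per_depth)
  })

  ## --- capillary density from angiogram ------------------------------------
  density <- with_stage("density", {
    ang <- gen_angiogram(capillary_density_pct = config$capillary_density_pct,
                         seed = child_seed(seed, 5L))
    capillary_density_angiogram(ang)
  })

  list(vascular = vascular, tissue = tissue, capillaries = capillaries,
       budget = budget, density = density)
}

#' Run the full cohort analysis
#'
#' Simulates every modality for each requested age group (at desk scale by
#' default), runs all analysis stages - vascular oximetry, tissue mapping,
#' capillary flowmetry, velocity-volume flowmetry, Krogh fitting and the
#' oxygen budget - and compares the groups with ANOVA + Tukey HSD.  The
#' run is a pure function of the seed: repeated runs give byte-identical
#' reports.
#'
#' @param groups age groups to simulate.
#' @param seed master integer seed.
#' @param n_vessels vessels per type per group (desk scale default 8).
#' @param n_capillaries capillaries per group (desk scale default 12).
#' @return object of class `cohort_report`.
#' @export
run_cohort_analysis <- function(groups = c("young", "middle", "old"),
                                seed = 1L, n_vessels = 8L,
                                n_capillaries = 12L) {
  res <- lapply(groups, function(g) {
    cfg <- make_cohort_config(g, seed = child_seed(seed, match(g, c("young", "middle", "old"))))
    simulate_group(cfg, n_vessels = n_vessels, n_capillaries = n_capillaries)
  })
  names(res) <- groups
  comparisons <- list()
  if (length(groups) >= 2L) {
    pull <- function(fun) lapply(res, fun)
    comparisons$arteriolar_po2 <- anova_tukey(pull(function(r) {
      pv <- r$vascular$per_vessel
      pv$po2_mmHg[pv$type == "arteriole"]
    }))
    comparisons$venular_po2 <- anova_tukey(pull(function(r) {
      pv <- r$vascular$per_vessel
      pv$po2_mmHg[pv$type == "venule"]
    }))
    comparisons$capillary_speed <- anova_tukey(pull(function(r)
      r$capillaries$table$speed_um_s))
  }
  summary_df <- do.call(rbind, lapply(groups, function(g) {
    r <- res[[g]]
    data.frame(
      group = g,
      po2_art_mmHg = r$vascular$po2_art_mean,
      po2_ven_mmHg = r$vascular$po2_ven_mean,
      oef = r$vascular$oef$oef,
      tissue_po2_mmHg = r$tissue$mean_po2,
      tissue_cv = r$tissue$cv,
      hypoxic_fraction = r$tissue$hypoxic_fraction,
      n_pockets = r$tissue$n_pockets,
      cbf_ml_g_min = r$budget$cbf_est,
      cmro2_umol_g_min = r$budget$cmro2_est,
      oc_umol_ml_min = r$budget$oc_mean,
      supply_fraction = r$budget$supply_fraction,
      capillary_density_pct = r$density$mean_capillary_pct)
  }))
  structure(list(schema_version = "1", seed = seed, groups = res,
                 summary = summary_df, comparisons = comparisons),
            class = "cohort_report")
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (the full report) plus flat CSV tables with units
#' in the column names: `summary.csv`, `vascular.csv`, `capillaries.csv`,
#' `flow_depth.csv` and `comparisons.csv`.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory (created if needed).
#' @return invisible vector of files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  jpath <- file.path(out_dir, "report.json")
  jsonlite::write_json(strip_classes(report), jpath, digits = NA,
                       auto_unbox = TRUE, na = "null", force = TRUE)
  files <- c(files, jpath)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write_csv_exact(df, p)
    files <<- c(files, p)
  }
  wr(report$summary, "summary.csv")
  if (length(report$groups)) {
    vas <- do.call(rbind, lapply(names(report$groups), function(g) {
      df <- report$groups[[g]]$vascular$per_vessel
      df$group <- g
      df
    }))
    wr(vas, "vascular.csv")
    caps <- do.call(rbind, lapply(names(report$groups), function(g) {
      df <- report$groups[[g]]$capillaries$table
      df$group <- g
      df
    }))
    wr(caps, "capillaries.csv")
    fd <- do.call(rbind, lapply(names(report$groups), function(g) {
      df <- report$groups[[g]]$budget$depth_profile
      df$group <- g
      df
    }))
    wr(fd, "flow_depth.csv")
  }
  if (length(report$comparisons)) {
    cmp <- do.call(rbind, lapply(names(report$comparisons), function(v) {
      df <- report$comparisons[[v]]$tukey
      df$variable <- v
      df$anova_p <- report$comparisons[[v]]$anova_p
      df
    }))
    wr(cmp, "comparisons.csv")
  }
  invisible(files)
}

# drop S3 classes recursively so jsonlite serializes plain structures
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}

#' @rdname write_report
#' @param path path to a `report.json` written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
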