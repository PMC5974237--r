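# Group statistics: one-way ANOVA with Tukey HSD post hoc comparisons and
# the significance-star annotation used throughout the reports.

#' Significance stars
#'
#' Star convention: `*****` p < 1e-5, `****` p < 1e-4, `***` p < 1e-3,
#' `**` p < 0.01, `*` p < 0.05, `#` p < 0.1 (approaches significance),
#' `ns` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-5) "*****"
    else if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else if (x < 0.1) "#"
    else "ns"
  }, character(1))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return object of class `group_comparison`: list with `summary`
#'   (per-group n/mean/sem), `anova_f`, `anova_p`, and `tukey` (data frame
#'   of all k(k-1)/2 pairwise comparisons with adjusted p-values and
#'   stars).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2L) stopf("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stopf("every group needs n >= 2")
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L)
    stopf("zero within-group variance in all groups")
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), ns), levels = names(groups)))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stars = significance_stars(tk[, "p adj"]),
                      row.names = NULL)
  summary_df <- data.frame(
    group = names(groups), n = ns,
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, sem, numeric(1)), row.names = NULL)
  structure(list(summary = summary_df,
                 anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tukey),
            class = "group_comparison")
}
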