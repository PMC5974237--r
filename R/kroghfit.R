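# Krogh cylinder model: forward evaluation and fitting of periarteriolar
# tissue pO2 profiles to estimate the net oxygen consumption rate (OC),
# the arteriolar pO2 and the tissue cylinder radius Rt.

# bracket term of the Krogh solution, per-second consumption already folded
# into the leading coefficient by the callers
krogh_bracket <- function(r, r_art, r_t) {
  rr <- pmin(r, r_t)
  (rr^2 - r_art^2) - 2 * r_t^2 * log(rr / r_art)
}

#' Krogh cylinder radial pO2 profile
#'
#' Steady-state oxygen tension at radius `r` from the axis of an arteriole
#' of radius `r_art` that supplies a tissue cylinder of radius `r_t` with a
#' uniform net volumetric consumption rate `oc`:
#' \deqn{pO2(r) = pO2_{art} + \frac{OC}{4 \alpha D}
#'   [(r^2 - R_{art}^2) - 2 R_t^2 \ln(r / R_{art})]}
#' For `r > r_t` the profile continues at its plateau value `pO2(r_t)`,
#' where the radial gradient vanishes.  `oc` is expressed in
#' umol O2 ml^-1 min^-1 and converted to per-second units internally
#' (`alpha` and `D` are per-second constants).
#'
#' @param r radial distance(s) from the arteriole axis, um (`r >= r_art`).
#' @param oc net oxygen consumption rate, umol O2 ml^-1 min^-1.
#' @param po2_art pO2 at the arteriolar wall, mmHg.
#' @param r_art arteriolar radius, um.
#' @param r_t tissue cylinder radius, um (> `r_art`).
#' @param constants an [oxygen_constants()].
#' @return pO2 at each `r`, mmHg.
#' @export
#' @examples
#' krogh_po2(50, oc = 1, po2_art = 90, r_art = 10, r_t = 100)  # ~65.6 mmHg
krogh_po2 <- function(r, oc, po2_art, r_art, r_t,
                      constants = oxygen_constants()) {
  if (r_t <= r_art || r_art <= 0) stopf("need r_t > r_art > 0")
  if (any(r < r_art)) stopf("r must be >= r_art (inside the vessel lumen)")
  oc_s <- oc / 60  # per-minute -> per-second
  po2_art + oc_s / (4 * constants$alpha * constants$D) *
    krogh_bracket(r, r_art, r_t)
}

#' Fit the Krogh model to a periarteriolar pO2 profile
#'
#' Nonlinear least squares over `(oc, po2_art, r_t)`.  For a fixed `r_t`
#' the model is linear in `oc` and `po2_art`, so the fit reduces to a 1-D
#' search over `r_t`: a coarse grid over the bounds followed by golden
#' section refinement, with an exact linear solve at every candidate.
#' Points beyond the candidate `r_t` contribute through the constant
#' plateau extension, so the plateau region informs `r_t`.
#'
#' @param r radial distances, um.
#' @param po2 measured pO2, mmHg.
#' @param r_art arteriolar radius, um (fixed, not fitted).
#' @param constants an [oxygen_constants()].
#' @param rt_bounds lower/upper bounds for `r_t`, um
#'   (default `c(r_art + 5, 300)`).
#' @param n_grid number of coarse grid points over the bounds.
#' @return object of class `krogh_fit`: list with `oc`
#'   (umol ml^-1 min^-1), `po2_art` (mmHg), `r_t` (um), `r_art`, `rms`
#'   (mmHg), `n_points` and `rt_at_bound` (TRUE when the optimum pinned at
#'   a bound, flagging an unreliable fit).
#' @export
fit_krogh <- function(r, po2, r_art, constants = oxygen_constants(),
                      rt_bounds = c(r_art + 5, 300), n_grid = 40L) {
  if (length(r) != length(po2)) stopf("r and po2 lengths differ")
  if (length(r) < 6L) stopf("need at least 6 points, got %d", length(r))
  if (diff(range(r)) < 60) stopf("profile must span at least 60 um of r")
  if (any(r < r_art)) stopf("all r must be >= r_art")
  coef_unit <- 1 / (60 * 4 * constants$alpha * constants$D)
  solve_at <- function(rt) {
    g <- coef_unit * krogh_bracket(r, r_art, rt)
    fit <- stats::lm(po2 ~ g)
    list(rss = sum(stats::residuals(fit)^2),
         po2_art = unname(stats::coef(fit)[1]),
         oc = unname(stats::coef(fit)[2]))
  }
  rss_at <- function(rt) solve_at(rt)$rss
  grid <- seq(rt_bounds[1], rt_bounds[2], length.out = n_grid)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  k <- which.min(rss_grid)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(n_grid, k + 1L)]
  opt <- stats::optimize(rss_at, lower = lo, upper = hi, tol = 1e-4)
  # keep whichever of the grid optimum / refined optimum is better
  rt_best <- if (opt$objective <= rss_grid[k]) opt$minimum else grid[k]
  sol <- solve_at(rt_best)
  at_bound <- (rt_best - rt_bounds[1]) < 0.5 || (rt_bounds[2] - rt_best) < 0.5
  structure(list(oc = sol$oc, po2_art = sol$po2_art, r_t = rt_best,
                 r_art = r_art, rms = sqrt(sol$rss / length(r)),
                 n_points = length(r), rt_at_bound = at_bound),
            class = "krogh_fit")
}

#' Summary statistics over a set of Krogh fits
#'
#' Mean, s.e.m. and coefficient of variation of OC and Rt across fitted
#' arterioles.  Fits whose `r_t` pinned at a bound are excluded and their
#' count reported.
#'
#' @param fits list of `krogh_fit` objects.
#' @return list with `oc` and `r_t` summaries (`mean`, `sem`, `cv`, `n`)
#'   and `n_excluded`.
#' @export
oc_statistics <- function(fits) {
  stopifnot(length(fits) >= 3L)
  bad <- vapply(fits, function(f) isTRUE(f$rt_at_bound), logical(1))
  keep <- fits[!bad]
  if (length(keep) == 0L) stopf("all fits excluded (r_t at bound)")
  oc <- vapply(keep, `[[`, numeric(1), "oc")
  rt <- vapply(keep, `[[`, numeric(1), "r_t")
  summ <- function(x) list(mean = mean(x), sem = sem(x), cv = cv(x),
                           n = length(x))
  list(oc = summ(oc), r_t = summ(rt), n_excluded = sum(bad))
}
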