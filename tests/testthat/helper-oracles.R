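# Independent oracles used by the tests.  These deliberately use different
# algorithms from the package code paths they check.

# Krogh radial profile by direct numerical integration of the flux balance:
# alpha D (1/r) d/dr (r dP/dr) = OC  with  P(r_art) = p_art, P'(r_t) = 0
# gives P'(r) = OC / (2 alpha D) * (r - r_t^2 / r); integrate with a fine
# trapezoid rule.  OC in umol/ml/min.
oracle_krogh <- function(r, oc, po2_art, r_art, r_t,
                         alpha = 1.27e-3, D = 4000, n_steps = 20000L) {
  oc_s <- oc / 60
  r_end <- min(r, r_t)
  if (r_end <= r_art) return(po2_art)
  rr <- seq(r_art, r_end, length.out = n_steps)
  dP <- oc_s / (2 * alpha * D) * (rr - r_t^2 / rr)
  po2_art + sum((dP[-1] + dP[-n_steps]) / 2) * (r_end - r_art) / (n_steps - 1)
}

# brute-force union-find single-linkage clustering of points within a
# linkage radius
oracle_union_find <- function(xyz, radius) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    dm <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (dm[i, j] <= radius) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# point-to-polyline distance by dense resampling of the polyline
oracle_polyline_dist <- function(p, poly, step = 0.01) {
  best <- Inf
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len / step)))
    for (t in ts) {
      q <- a + t * (b - a)
      best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}

# a small noise-free decay trace with known lifetime
make_exact_trace <- function(tau = 30, A = 5, B = 0.1, n = 100, t_max = 275) {
  t <- seq(0.5, t_max, length.out = n)
  structure(list(t_us = t, counts = A * exp(-t / tau) + B, n_cycles = 1L),
            class = "decay_trace")
}
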