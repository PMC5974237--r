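# Internal helpers shared across modules.

#' @importFrom stats sd coef lm nls optimize rnorm rpois rexp runif rbinom
#'   predict aov TukeyHSD pf pt var complete.cases setNames quantile median
#' @importFrom utils read.csv write.csv head tail
NULL

# standard error of the mean (sample SD / sqrt(n))
sem <- function(x) stats::sd(x) / sqrt(length(x))

# coefficient of variation with sample (n-1) SD
cv <- function(x) stats::sd(x) / mean(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum distance from points to a 3D polyline
#'
#' Exact point-to-segment distances, minimized over all segments of the
#' polyline.
#'
#' @param pts numeric matrix (n x 3) of query points, micrometres.
#' @param poly numeric matrix (m x 3) of polyline vertices in order.
#' @return numeric vector of n distances (micrometres).
#' @keywords internal
dist_to_polyline <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  poly <- matrix(as.numeric(poly), ncol = 3)
  n <- nrow(pts)
  if (nrow(poly) == 1L) {
    d2 <- (pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2 +
      (pts[, 3] - poly[1, 3])^2
    return(sqrt(d2))
  }
  best <- rep(Inf, n)
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]
    b <- poly[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap1 <- pts[, 1] - a[1]
    ap2 <- pts[, 2] - a[2]
    ap3 <- pts[, 3] - a[3]
    if (len2 == 0) {
      d2 <- ap1^2 + ap2^2 + ap3^2
    } else {
      t <- (ap1 * ab[1] + ap2 * ab[2] + ap3 * ab[3]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (ap1 - t * ab[1])^2 + (ap2 - t * ab[2])^2 + (ap3 - t * ab[3])^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Connected components of TRUE cells in a logical matrix (4-connectivity).
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  # edges between horizontally / vertically adjacent TRUE cells
  i <- ((idx - 1L) %% nr) + 1L
  j <- ((idx - 1L) %/% nr) + 1L
  cand_r <- idx[j < nc]
  right <- cand_r[mask[cand_r + nr]]
  cand_d <- idx[i < nr]
  down <- cand_d[mask[cand_d + 1L]]
  edges <- rbind(cbind(right, right + nr), cbind(down, down + 1L))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx))
  )
  comp <- igraph::components(g)
  lab[as.integer(igraph::V(g)$name)] <- comp$membership
  lab
}

# Majority filter for a binary matrix: a cell becomes TRUE when more than
# half of the valid cells in its k x k neighbourhood are TRUE.  Equivalent to
# a median filter on a binary image.  Implemented with an integral image so
# large kernels stay cheap; the window shrinks at the border.
binary_median <- function(mask, k) {
  if (k %% 2L == 0L) k <- k + 1L
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (k > nr || k > nc) stopf("median kernel (%d) larger than image (%d x %d)", k, nr, nc)
  h <- (k - 1L) %/% 2L
  # integral images of the mask and of an all-ones matrix (valid-cell counts)
  local_sum <- function(m) {
    cs <- apply(rbind(0, m), 2, cumsum)
    cs <- t(apply(cbind(0, cs), 1, cumsum))
    i0 <- pmax(seq_len(nr) - h, 1L)
    i1 <- pmin(seq_len(nr) + h, nr)
    j0 <- pmax(seq_len(nc) - h, 1L)
    j1 <- pmin(seq_len(nc) + h, nc)
    cs[i1 + 1L, j1 + 1L] - cs[i0, j1 + 1L] - cs[i1 + 1L, j0] + cs[i0, j0]
  }
  s <- local_sum(matrix(as.numeric(mask), nr, nc))
  n <- local_sum(matrix(1, nr, nc))
  s > n / 2
}

# deterministic child seed derived from a parent seed and a stream index;
# kept well below 2^31
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483) + 1L
}
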