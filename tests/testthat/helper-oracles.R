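# Independent oracle implementations used to validate the package's
# statistics and optimizer. These deliberately take the slow, direct
# route (double loops, dense matrices, exhaustive enumeration) and share
# no code with the implementations under test.

# dense symmetric adjacency from a spot_graph
dense_adjacency <- function(g) {
  A <- matrix(0, g$n, g$n)
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges$from[e]; j <- g$edges$to[e]
    A[i, j] <- A[i, j] + g$edges$weight[e]
    A[j, i] <- A[j, i] + g$edges$weight[e]
  }
  A
}

# Moran's I by explicit double loop
oracle_morans <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  s0 <- 0; num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s0 <- s0 + W[i, j]
    num <- num + W[i, j] * z[i] * z[j]
  }
  n / s0 * num / sum(z^2)
}

row_normalize_dense <- function(A) {
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

# RB-configuration quality by direct evaluation of the double sum
oracle_rb <- function(A, membership, gamma) {
  n <- nrow(A)
  k <- rowSums(A)
  twom <- sum(k)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + A[i, j]
      if (twom > 0) q <- q - gamma * k[i] * k[j] / twom
    }
  }
  q
}

# all set partitions of n elements via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(), 0L)
  out
}

# exhaustive multiplex optimum over all partitions; quality is linear in
# the layers, so the per-pair contributions collapse into one matrix
oracle_multiplex_optimum <- function(adjs, weights, gammas) {
  n <- nrow(adjs[[1]])
  M <- matrix(0, n, n)
  for (l in seq_along(adjs)) {
    k <- rowSums(adjs[[l]])
    twom <- sum(k)
    null <- if (twom > 0) gammas[l] * outer(k, k) / twom else 0
    M <- M + weights[l] * (adjs[[l]] - null)
  }
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- sum(M[outer(p, p, "==")])
    if (q > best) best <- q
  }
  best
}

# random seeded 2-layer multiplex instance on <= 8 nodes
random_multiplex_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  layers <- list(); adjs <- list()
  weights <- stats::runif(2, 0.2, 2)
  gammas <- stats::runif(2, 0.5, 1.5)
  for (l in 1:2) {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < 0.5
    if (!any(keep)) keep[sample(ncol(pairs), 1)] <- TRUE
    w <- round(stats::runif(sum(keep), 0.2, 2), 2)
    g <- spot_graph(n, pairs[1, keep], pairs[2, keep], weight = w)
    layers[[l]] <- layer_spec(g, weights[l], gammas[l])
    adjs[[l]] <- dense_adjacency(g)
  }
  list(n = n, layers = layers, adjs = adjs, weights = weights, gammas = gammas)
}

# exact two-sided Wilcoxon signed-rank p-value by full 2^n enumeration
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# ARI from raw pair counts (no contingency table)
oracle_ari <- function(a, b) {
  n <- length(a)
  up <- upper.tri(matrix(0, n, n))
  sa <- outer(a, a, "==")[up]
  sb <- outer(b, b, "==")[up]
  n11 <- as.numeric(sum(sa & sb)); n10 <- as.numeric(sum(sa & !sb))
  n01 <- as.numeric(sum(!sa & sb)); n00 <- as.numeric(sum(!sa & !sb))
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# NMI (arithmetic normalization) by explicit probability sums
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0
  for (u in ua) { p <- mean(a == u); ha <- ha - p * log(p) }
  hb <- 0
  for (u in ub) { p <- mean(b == u); hb <- hb - p * log(p) }
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (u in ua) for (v in ub) {
    pj <- mean(a == u & b == v)
    if (pj > 0) mi <- mi + pj * log(pj / (mean(a == u) * mean(b == v)))
  }
  mi / ((ha + hb) / 2)
}

# Delaunay edges by brute-force empty-circumcircle test over all triples
# (general-position point sets only)
oracle_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  edges <- matrix(integer(), ncol = 2)
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 > r2 * (1 + 1e-9))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_set <- function(g) {
  paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
}

# small helper: expression matrix from a dense numeric matrix
make_expr <- function(m, layer_tag = "raw") {
  expression_matrix(m, layer_tag = layer_tag)
}
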