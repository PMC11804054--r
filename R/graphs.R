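#' Undirected weighted graph over spots
#'
#' Edge-list representation used for both the physical-space and the
#' latent-space layer. Nodes are 1-based integers aligned to the row order
#' of the originating coordinates/matrix; edges are stored once with
#' `from < to`. Weights are strictly positive; an optional `distance`
#' column carries the Euclidean edge length.
#'
#' @param n number of nodes.
#' @param from,to integer node indices in `1..n`.
#' @param weight positive edge weights.
#' @param distance optional non-negative distances.
#' @return An object of class `spot_graph`.
#' @export
spot_graph <- function(n, from = integer(), to = integer(),
                       weight = numeric(), distance = NULL) {
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != length(to) || length(from) != length(weight))
    stop_sm("from, to and weight must have equal length")
  if (length(from)) {
    if (min(c(from, to)) < 1L || max(c(from, to)) > n)
      stop_sm("edge endpoints outside 1..%d", n)
    if (any(from == to)) stop_sm("self-loops are not allowed")
    if (any(!is.finite(weight)) || any(weight <= 0))
      stop_sm("edge weights must be finite and > 0")
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    if (anyDuplicated(cbind(from, to))) stop_sm("duplicate edges")
  }
  edges <- data.frame(from = from, to = to, weight = as.numeric(weight))
  if (!is.null(distance)) {
    if (length(distance) != length(from)) stop_sm("distance length mismatch")
    if (any(!is.finite(distance)) || any(distance < 0))
      stop_sm("distances must be finite and >= 0")
    edges$distance <- as.numeric(distance)
  }
  structure(list(n = as.integer(n), edges = edges), class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("spot_graph: %d nodes, %d edges%s\n", x$n, nrow(x$edges),
              if (!is.null(x$edges$distance)) " (with distances)" else ""))
  invisible(x)
}

#' Number of edges / node degrees of a spot graph
#'
#' @param g a [spot_graph].
#' @param weighted if `TRUE`, weighted degree (strength), else edge count.
#' @return numeric vector of length `g$n`.
#' @export
graph_degree <- function(g, weighted = TRUE) {
  w <- if (weighted) g$edges$weight else rep(1, nrow(g$edges))
  deg <- numeric(g$n)
  if (nrow(g$edges)) {
    t1 <- tapply(w, g$edges$from, sum)
    t2 <- tapply(w, g$edges$to, sum)
    deg[as.integer(names(t1))] <- deg[as.integer(names(t1))] + t1
    deg[as.integer(names(t2))] <- deg[as.integer(names(t2))] + t2
  }
  deg
}

#' Symmetric sparse adjacency matrix of a spot graph
#'
#' @param g a [spot_graph].
#' @param row_normalize divide each row by its sum (rows of isolated nodes
#'   stay zero).
#' @return A [Matrix::dgCMatrix-class] of dimension `n x n`.
#' @export
adjacency_matrix <- function(g, row_normalize = FALSE) {
  A <- Matrix::sparseMatrix(i = c(g$edges$from, g$edges$to),
                            j = c(g$edges$to, g$edges$from),
                            x = c(g$edges$weight, g$edges$weight),
                            dims = c(g$n, g$n))
  if (row_normalize) {
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1
    A <- Matrix::Diagonal(x = 1 / rs) %*% A
  }
  methods::as(A, "CsparseMatrix")
}

dedup_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- !duplicated(cbind(a, b))
  list(from = a[keep], to = b[keep])
}

#' Spatial neighbor graph for spots on a regular lattice
#'
#' Connects each spot to its equidistant lattice neighbors: 6 for a
#' hexagonal grid, 4 for a square grid. All edges get weight 1
#' (neighbors on a grid are equidistant, so no distance transform is
#' applied). The lattice spacing is estimated as the minimum pairwise
#' distance; pairs within a relative tolerance of that spacing become
#' edges.
#'
#' @param coords a [spot_coordinates] table on a (possibly incomplete)
#'   lattice.
#' @param grid_type `"hex"` or `"square"`; default chosen from the
#'   coordinates' technology tag.
#' @param tol relative tolerance for matching the lattice spacing.
#' @return A [spot_graph] with unit weights.
#' @export
build_grid_graph <- function(coords, grid_type = NULL, tol = 1e-3) {
  stopifnot(inherits(coords, "spot_coordinates"))
  if (is.null(grid_type)) {
    tech <- attr(coords, "technology")
    grid_type <- switch(tech, hex_grid = "hex", square_grid = "square",
                        stop_sm("grid_type required for technology '%s'", tech))
  }
  grid_type <- match.arg(grid_type, c("hex", "square"))
  n <- nrow(coords)
  if (n < 2) return(spot_graph(n))
  if (anyDuplicated(cbind(coords$x, coords$y)))
    stop_sm("duplicate coordinates cannot lie on a lattice")
  pr <- pairs_within_factor(coords$x, coords$y, factor = 1 + 10 * tol)
  if (!length(pr$from)) stop_sm("coordinates not resolvable to a lattice")
  s <- min(pr$dist)
  keep <- abs(pr$dist - s) <= tol * s
  g <- spot_graph(n, pr$from[keep], pr$to[keep],
                  weight = rep(1, sum(keep)))
  max_deg <- if (grid_type == "hex") 6L else 4L
  deg <- graph_degree(g, weighted = FALSE)
  if (max(deg) > max_deg)
    stop_sm("node degree %d exceeds %d: coordinates do not form a %s lattice",
            max(deg), max_deg, grid_type)
  if (mean(deg == 0) > 0.1)
    stop_sm("%d of %d spots have no equidistant neighbor: coordinates not resolvable to a lattice",
            sum(deg == 0), n)
  g
}

# All pairs within `factor * s_min` of each other, where s_min is the
# minimum nearest-neighbor distance, found by bucketing into cells so the
# scan stays near-linear in n.
pairs_within_factor <- function(x, y, factor = 1.01) {
  n <- length(x)
  # cell size: estimate nearest-neighbor spacing from a sample
  idx <- if (n > 200) sort(sample.int(n, 200)) else seq_len(n)
  dmin <- Inf
  for (i in idx) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    dmin <- min(dmin, sqrt(min(d2)))
  }
  if (!is.finite(dmin) || dmin == 0) stop_sm("degenerate coordinates")
  r <- factor * dmin
  cx <- floor(x / r); cy <- floor(y / r)
  key <- paste(cx, cy)
  cell <- split(seq_len(n), key)
  from <- integer(); to <- integer(); dist <- numeric()
  for (members in cell) {
    kx <- cx[members[1]]; ky <- cy[members[1]]
    cand <- unlist(lapply(-1:1, function(dx) lapply(-1:1, function(dy) {
      cell[[paste(kx + dx, ky + dy)]]
    })), use.names = FALSE)
    for (i in members) {
      j <- cand[cand > i]
      if (!length(j)) next
      d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      ok <- d <= r
      from <- c(from, rep(i, sum(ok))); to <- c(to, j[ok]); dist <- c(dist, d[ok])
    }
  }
  list(from = from, to = to, dist = dist)
}

#' k-nearest-neighbor graph in physical or latent space
#'
#' Builds the directed kNN relation by Euclidean distance and symmetrizes
#' it by union (an edge exists if either endpoint selects the other). Edge
#' weights default to 1; the Euclidean distance is stored in the
#' `distance` attribute for a later [distances_to_connectivities()]
#' transform.
#'
#' @param points numeric matrix, one row per node (any dimension >= 1).
#' @param k number of neighbors; clipped to `n - 1` with a warning.
#' @return A [spot_graph] with unit weights and a distance attribute.
#' @export
build_knn_graph <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop_sm("need at least 2 points")
  if (anyNA(points)) stop_sm("NaN/NA in point coordinates")
  if (!is_count(k)) stop_sm("k must be a positive integer")
  if (k >= n) {
    warn_sm("k = %d >= n = %d; clipping k to %d", k, n, n - 1)
    k <- n - 1L
  }
  nn <- knn_index(points, k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn$idx))
  d <- as.vector(t(nn$dist))
  key <- pmin(from, to) * (n + 1) + pmax(from, to)
  keep <- !duplicated(key)
  spot_graph(n, from[keep], to[keep], weight = rep(1, sum(keep)),
             distance = d[keep])
}

# exact kNN by blocked brute-force distance computation
knn_index <- function(points, k) {
  n <- nrow(points)
  sq <- rowSums(points^2)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * points[rows, , drop = FALSE] %*% t(points)
    d2[cbind(seq_along(rows), rows)] <- Inf
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[rows[r], ] <- o
      dst[rows[r], ] <- sqrt(d2[r, o])
    }
  }
  list(idx = idx, dist = dst)
}

#' Transform edge distances to connectivities
#'
#' Applies the linear transform `w = 1 - d / d_max`, with `d_max` the
#' maximum edge distance in the graph, so near neighbors get weights close
#' to 1. Edges attaining weight exactly 0 (those at `d_max`) are removed:
#' a zero-weight edge is a non-edge for modularity optimization.
#'
#' @param g a [spot_graph] whose edges carry a `distance` attribute.
#' @return A [spot_graph] with weights in `(0, 1]` and no distance
#'   attribute.
#' @export
distances_to_connectivities <- function(g) {
  stopifnot(inherits(g, "spot_graph"))
  if (!nrow(g$edges)) stop_sm("graph has no edges")
  if (is.null(g$edges$distance)) stop_sm("edges carry no distance attribute")
  dmax <- max(g$edges$distance)
  if (dmax <= 0) stop_sm("all edge distances are zero")
  w <- 1 - g$edges$distance / dmax
  keep <- w > 0
  if (!any(keep))
    stop_sm("degenerate transform: all edges at d_max; use unit weights instead")
  spot_graph(g$n, g$edges$from[keep], g$edges$to[keep], weight = w[keep])
}

#' Latent-space neighbor graph with a local-scaling Gaussian kernel
#'
#' Builds the union-symmetrized kNN graph in a latent (e.g. PCA) space and
#' weights each edge by `exp(-d^2 / (sigma_i * sigma_j))`, where `sigma_i`
#' is the distance from node `i` to its k-th neighbor (local scaling).
#' With `kernel = "binary"` all edges get weight 1.
#'
#' @param latent numeric matrix of latent coordinates, one row per spot.
#' @param k number of neighbors (default 15).
#' @param kernel `"local_gaussian"` (default) or `"binary"`.
#' @return A [spot_graph] with weights in `(0, 1]`.
#' @export
build_latent_knn <- function(latent, k = 15,
                             kernel = c("local_gaussian", "binary")) {
  kernel <- match.arg(kernel)
  latent <- as.matrix(latent)
  if (anyNA(latent)) stop_sm("NaN/NA in latent vectors")
  g <- build_knn_graph(latent, k)
  if (kernel == "binary") {
    return(spot_graph(g$n, g$edges$from, g$edges$to,
                      weight = rep(1, nrow(g$edges))))
  }
  k_eff <- min(k, g$n - 1L)
  nn <- knn_index(latent, k_eff)
  sigma <- nn$dist[, k_eff]
  d <- g$edges$distance
  ss <- sigma[g$edges$from] * sigma[g$edges$to]
  w <- ifelse(d == 0, 1, exp(-d^2 / pmax(ss, 1e-300)))
  w <- pmax(w, 1e-300)  # keep strictly positive
  spot_graph(g$n, g$edges$from, g$edges$to, weight = w)
}

#' Read / write a spot graph as an edge-list TSV
#'
#' Columns `u`, `v`, `weight` and optionally `distance`; node indices are
#' 0-based on disk.
#'
#' @param g a [spot_graph].
#' @param path file path.
#' @param n number of nodes (required on read, since isolated nodes leave
#'   no trace in an edge list).
#' @export
write_graph <- function(g, path) {
  df <- data.frame(u = g$edges$from - 1L, v = g$edges$to - 1L,
                   weight = g$edges$weight)
  if (!is.null(g$edges$distance)) df$distance <- g$edges$distance
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path, n) {
  if (!file.exists(path)) stop_sm("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  spot_graph(n, df$u + 1L, df$v + 1L, weight = df$weight,
             distance = df$distance)
}
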