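#' One clustering layer of a multiplex
#'
#' Bundles a graph with its layer weight and resolution. All layers of a
#' multiplex must share the node set; only the ratio of layer weights
#' matters for the optimum.
#'
#' @param graph a [spot_graph].
#' @param weight real layer weight (>= 0 in normal use).
#' @param resolution positive resolution parameter; higher values favor
#'   more, smaller clusters.
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(graph, weight = 1, resolution = 1) {
  stopifnot(inherits(graph, "spot_graph"))
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight))
    stop_sm("layer weight must be a finite scalar")
  if (!is.numeric(resolution) || resolution <= 0)
    stop_sm("resolution must be positive")
  structure(list(graph = graph, weight = weight, resolution = resolution),
            class = "layer_spec")
}

#' RB-configuration quality of a partition
#'
#' The resolution-parameterized modularity
#' `Q(gamma) = sum_ij (A_ij - gamma k_i k_j / (2m)) delta(c_i, c_j)`
#' over ordered node pairs, with `k` the weighted degree and `2m` the
#' total degree; unnormalized, so its units are edge-weight units. At
#' `gamma = 1` this is (unnormalized) Newman-Girvan modularity.
#'
#' @param g a [spot_graph].
#' @param membership cluster id per node (any coding).
#' @param gamma resolution parameter.
#' @return The scalar quality.
#' @export
rb_quality <- function(g, membership, gamma = 1) {
  stopifnot(inherits(g, "spot_graph"))
  if (g$n < 1) stop_sm("empty graph")
  if (length(membership) != g$n)
    stop_sm("membership length %d != %d nodes", length(membership), g$n)
  if (anyNA(membership)) stop_sm("membership contains NA")
  m <- as.integer(factor(membership))
  same <- m[g$edges$from] == m[g$edges$to]
  in_sum <- 2 * sum(g$edges$weight[same])  # ordered pairs
  deg <- graph_degree(g)
  twom <- sum(deg)
  nul <- if (twom > 0) gamma * sum(tapply(deg, m, sum)^2) / twom else 0
  in_sum - nul
}

#' Combined quality of a multiplex partition
#'
#' `Q_total = sum_l w_l Q_l(gamma_l)`, the weighted sum of per-layer
#' [rb_quality()] values.
#'
#' @param layers list of [layer_spec] objects on a shared node set.
#' @param membership cluster id per node.
#' @return The scalar combined quality.
#' @export
multiplex_quality <- function(layers, membership) {
  check_layers(layers)
  sum(vapply(layers, function(l)
    l$weight * rb_quality(l$graph, membership, l$resolution), numeric(1)))
}

check_layers <- function(layers) {
  if (!length(layers)) stop_sm("at least one layer required")
  if (inherits(layers, "layer_spec")) stop_sm("wrap layers in a list")
  ns <- vapply(layers, function(l) l$graph$n, integer(1))
  if (length(unique(ns)) != 1)
    stop_sm("layers disagree on node count: %s", paste(ns, collapse = ", "))
  if (all(vapply(layers, function(l) l$weight == 0, logical(1))))
    stop_sm("all layer weights are zero")
  invisible(ns[1])
}

#' Multiplex Leiden clustering
#'
#' Finds a single partition of the shared node set that maximizes the
#' weighted multiplex quality (see [multiplex_quality()]) by the Leiden
#' procedure: seeded queue-based local moving, refinement within
#' communities, and simultaneous aggregation of all layers, iterated
#' until a pass yields no quality increase. Quality is non-decreasing
#' across passes by construction; this is asserted on every run.
#'
#' @param layers list of [layer_spec] objects.
#' @param seed integer seed controlling node visit order; same seed gives
#'   identical membership.
#' @param max_passes cap on local-move/aggregation passes (default 100).
#' @param n_restarts number of seeded optimizer starts; the best-quality
#'   partition wins (ties: first). Defaults to 8 on small problems
#'   (<= 256 nodes), where the greedy search is cheap and local optima
#'   matter most, and 1 otherwise. Restart seeds are derived from `seed`,
#'   so the result is still deterministic.
#' @return A `leiden_partition`: list with `membership` (0-based,
#'   contiguous), `n_clusters`, `quality`, `quality_trace`, `passes`.
#' @export
leiden_multiplex <- function(layers, seed = 0, max_passes = 100,
                             n_restarts = NULL) {
  n <- check_layers(layers)
  n_restarts <- n_restarts %||% (if (n <= 256) 8L else 1L)
  ll <- lapply(layers, function(l)
    list(from = l$graph$edges$from - 1L, to = l$graph$edges$to - 1L,
         weight = l$graph$edges$weight))
  lw <- vapply(layers, `[[`, numeric(1), "weight")
  lres <- vapply(layers, `[[`, numeric(1), "resolution")
  best <- NULL
  for (i in seq_len(n_restarts)) {
    s <- if (i == 1L) as.integer(seed) else derive_seed(seed, paste0("restart", i))
    res <- leiden_multiplex_cpp(ll, n, lw, lres, s, as.integer(max_passes))
    if (!res$monotone)
      stop_sm("internal error: quality decreased during optimization")
    if (is.null(best) || res$quality > best$quality + 1e-12) best <- res
  }
  structure(list(membership = best$membership, n_clusters = best$n_clusters,
                 quality = best$quality, quality_trace = best$quality_trace,
                 passes = best$passes, seed = seed),
            class = "leiden_partition")
}

#' @export
print.leiden_partition <- function(x, ...) {
  cat(sprintf("leiden_partition: %d clusters over %d nodes, quality %.4f (%d passes)\n",
              x$n_clusters, length(x$membership), x$quality, x$passes))
  invisible(x)
}

#' Search the resolution that yields a target number of clusters
#'
#' Step search in resolution space: the resolution is increased by the
#' current step while the clustering yields too few clusters and
#' decreased while it yields too many; every direction flip halves the
#' step. Stops at the first resolution with exactly `target_k` clusters,
#' or returns the closest one found after `max_iter` evaluations with a
#' warning. `cluster_fn` must be deterministic in the resolution (fix the
#' seed inside).
#'
#' @param cluster_fn function(resolution) returning an object with an
#'   `n_clusters` element (e.g. a `leiden_partition`).
#' @param target_k desired number of clusters.
#' @param r_init starting resolution.
#' @param r_step initial step size.
#' @param max_iter maximum number of evaluations.
#' @return list(resolution, partition, n_clusters, iterations, converged).
#' @export
search_resolution <- function(cluster_fn, target_k, r_init = 1.0,
                              r_step = 0.1, max_iter = 40) {
  if (!is_count(target_k)) stop_sm("target_k must be a positive integer")
  r <- r_init
  step <- r_step
  last_dir <- 0L
  best <- NULL
  for (it in seq_len(max_iter)) {
    part <- cluster_fn(r)
    k <- part$n_clusters
    if (is.null(best) || abs(k - target_k) < abs(best$n_clusters - target_k))
      best <- list(resolution = r, partition = part, n_clusters = k,
                   iterations = it, converged = FALSE)
    if (k == target_k)
      return(list(resolution = r, partition = part, n_clusters = k,
                  iterations = it, converged = TRUE))
    dir <- if (k < target_k) 1L else -1L
    if (last_dir != 0L && dir != last_dir) step <- step / 2
    last_dir <- dir
    r <- r + dir * step
    if (r <= 0) {
      warn_sm("resolution search reached non-positive value; clamping to 1e-4")
      r <- 1e-4
    }
  }
  warn_sm("resolution search did not hit target_k = %d in %d iterations; closest k = %d",
          target_k, max_iter, best$n_clusters)
  best$iterations <- max_iter
  best
}

#' Spatially aware Leiden clustering
#'
#' Two-stage multiplex clustering of an expression latent-space graph and
#' a physical-space graph sharing the same spots. Stage one tunes the
#' latent layer's resolution with non-spatial Leiden until the target
#' number of clusters is reached; stage two holds that resolution and the
#' layer weights (1 for the latent layer, `spatial_weight` for the
#' spatial layer) fixed and tunes the spatial layer's resolution so the
#' joint multiplex clustering hits the target. Only the ratio of the two
#' layer weights matters.
#'
#' @param latent_graph [spot_graph] built in the expression latent space
#'   (see [build_latent_knn()]).
#' @param spatial_graph [spot_graph] over the same spots in physical
#'   space (see [build_grid_graph()], [build_delaunay_graph()],
#'   [build_knn_graph()]).
#' @param spatial_weight weight of the spatial layer relative to the
#'   latent layer's weight of 1; `0` reduces to non-spatial Leiden. The
#'   string `"match"` sets the weight to the ratio of total edge weight
#'   between the latent and the spatial layer, putting both layers on the
#'   same quality scale (the per-layer quality is unnormalized, so a layer
#'   with more total edge weight otherwise dominates).
#' @param target_k desired number of spatial domains.
#' @param seed integer seed used for every clustering in both searches.
#' @param r_init,r_step,max_iter passed to [search_resolution()].
#' @param max_passes passed to [leiden_multiplex()].
#' @return An object of class `spatialleiden`: list with `membership`
#'   (0-based), `n_clusters`, `quality`, `resolutions` (latent, spatial),
#'   `spatial_weight`, `nonspatial` (the stage-one `leiden_partition`),
#'   `converged`, `seed`, `call`.
#' @export
spatialleiden <- function(latent_graph, spatial_graph, spatial_weight = 1,
                          target_k, seed = 0, r_init = 1.0, r_step = 0.1,
                          max_iter = 40, max_passes = 100) {
  stopifnot(inherits(latent_graph, "spot_graph"),
            inherits(spatial_graph, "spot_graph"))
  if (latent_graph$n != spatial_graph$n)
    stop_sm("latent graph has %d nodes but spatial graph has %d",
            latent_graph$n, spatial_graph$n)
  if (identical(spatial_weight, "match")) {
    spatial_weight <- sum(latent_graph$edges$weight) /
      sum(spatial_graph$edges$weight)
  }
  if (!is.numeric(spatial_weight) || spatial_weight < 0)
    stop_sm("spatial_weight must be >= 0 or \"match\"")

  stage_a <- search_resolution(function(r)
    leiden_multiplex(list(layer_spec(latent_graph, 1, r)),
                     seed = seed, max_passes = max_passes),
    target_k, r_init = r_init, r_step = r_step, max_iter = max_iter)

  if (spatial_weight == 0) {
    out <- list(membership = stage_a$partition$membership,
                n_clusters = stage_a$n_clusters,
                quality = stage_a$partition$quality,
                quality_trace = stage_a$partition$quality_trace,
                passes = stage_a$partition$passes,
                resolutions = c(latent = stage_a$resolution, spatial = NA),
                spatial_weight = 0,
                nonspatial = stage_a$partition,
                converged = stage_a$converged,
                seed = seed, call = match.call())
    return(structure(out, class = "spatialleiden"))
  }

  stage_b <- search_resolution(function(r)
    leiden_multiplex(list(layer_spec(latent_graph, 1, stage_a$resolution),
                          layer_spec(spatial_graph, spatial_weight, r)),
                     seed = seed, max_passes = max_passes),
    target_k, r_init = stage_a$resolution, r_step = r_step,
    max_iter = max_iter)

  structure(list(membership = stage_b$partition$membership,
                 n_clusters = stage_b$n_clusters,
                 quality = stage_b$partition$quality,
                 quality_trace = stage_b$partition$quality_trace,
                 passes = stage_b$partition$passes,
                 resolutions = c(latent = stage_a$resolution,
                                 spatial = stage_b$resolution),
                 spatial_weight = spatial_weight,
                 nonspatial = stage_a$partition,
                 converged = stage_a$converged && stage_b$converged,
                 seed = seed, call = match.call()),
            class = "spatialleiden")
}

#' @export
print.spatialleiden <- function(x, ...) {
  cat(sprintf("spatialleiden: %d clusters over %d spots\n",
              x$n_clusters, length(x$membership)))
  cat(sprintf("  spatial weight %g; resolutions: latent %.4g, spatial %s\n",
              x$spatial_weight, x$resolutions["latent"],
              if (is.na(x$resolutions["spatial"])) "-" else
                format(x$resolutions["spatial"], digits = 4)))
  cat(sprintf("  multiplex quality %.4f%s\n", x$quality,
              if (x$converged) "" else " (target cluster count not reached)"))
  invisible(x)
}

#' @export
summary.spatialleiden <- function(object, ...) {
  sizes <- table(object$membership)
  cat(sprintf("spatialleiden fit: %d clusters, %d spots, spatial weight %g\n",
              object$n_clusters, length(object$membership),
              object$spatial_weight))
  cat("cluster sizes:\n")
  print(sizes)
  invisible(list(sizes = sizes, resolutions = object$resolutions,
                 quality = object$quality))
}

#' Plot a clustered tissue as a domain map
#'
#' @param x a `spatialleiden` fit (or any object with a `membership`
#'   element).
#' @param coords a [spot_coordinates] table aligned to the fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spatialleiden <- function(x, coords, ...) {
  stopifnot(nrow(coords) == length(x$membership))
  cols <- grDevices::hcl.colors(max(x$membership) + 1L, "Dark 3")
  graphics::plot(coords$x, coords$y, col = cols[x$membership + 1L],
                 pch = 19, cex = 0.6, asp = 1,
                 xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Write a partition as TSV (id, cluster), 0-based cluster ids
#'
#' @param part object with a `membership` element (0-based).
#' @param ids spot ids aligned to the membership.
#' @param path output path.
#' @export
write_partition <- function(part, ids, path) {
  utils::write.table(data.frame(id = as.character(ids),
                                cluster = part$membership),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
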