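two_triangles <- function() {
  spot_graph(6, c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6), weight = rep(1, 6))
}

bridged_cliques <- function() {
  # two 3-cliques joined by one bridge edge
  spot_graph(6, c(1, 1, 2, 4, 4, 5, 3), c(2, 3, 3, 5, 6, 6, 4),
             weight = rep(1, 7))
}

test_that("RB quality reproduces hand-derived values", {
  g <- two_triangles()
  part <- c(0, 0, 0, 1, 1, 1)
  expect_equal(rb_quality(g, part, gamma = 1), 12 - 72 / 12)  # = 6
  expect_equal(oracle_rb(dense_adjacency(g), part, 1), 6)
  # gamma = 0, single community: Q = 2m
  expect_equal(rb_quality(g, rep(0, 6), gamma = 0), 12)
  # singleton partition, gamma = 0, loop-free: Q = 0
  expect_equal(rb_quality(g, 0:5, gamma = 0), 0)
})

test_that("RB quality matches the double-sum oracle on random instances", {
  for (seed in 1:8) {
    inst <- random_multiplex_instance(seed)
    part <- sample(1:3, inst$n, replace = TRUE)
    for (l in 1:2) {
      expect_equal(rb_quality(inst$layers[[l]]$graph, part,
                              inst$layers[[l]]$resolution),
                   oracle_rb(inst$adjs[[l]], part, inst$gammas[l]),
                   tolerance = 1e-10)
    }
  }
})

test_that("multiplex quality is the weighted sum of layer qualities", {
  g <- two_triangles()
  part <- c(0, 0, 0, 1, 1, 1)
  q1 <- rb_quality(g, part, 1)
  expect_equal(multiplex_quality(list(layer_spec(g, 1, 1),
                                      layer_spec(g, 0, 1)), part), q1)
  expect_equal(multiplex_quality(list(layer_spec(g, 1, 1),
                                      layer_spec(g, 1, 1)), part), 2 * q1)
  expect_equal(multiplex_quality(list(layer_spec(g, 3.5, 1)), part), 3.5 * q1)
  g5 <- spot_graph(5, 1, 2, 1)
  expect_error(multiplex_quality(list(layer_spec(g, 1, 1),
                                      layer_spec(g5, 1, 1)), part),
               "node count")
})

test_that("optimizer finds the exact optimum of the bridged-cliques graph", {
  g <- bridged_cliques()
  p <- leiden_multiplex(list(layer_spec(g, 1, 1)), seed = 3)
  expect_equal(p$n_clusters, 2)
  expect_equal(p$membership[1:3], rep(p$membership[1], 3))
  expect_equal(p$membership[4:6], rep(p$membership[4], 3))
  expect_equal(p$quality, 12 - 98 / 14)  # = 5
  # exhaustive confirmation that 5 is the global optimum
  A <- dense_adjacency(g)
  expect_equal(oracle_multiplex_optimum(list(A), 1, 1), 5)
})

test_that("a zero-weight layer does not affect the partition", {
  g <- bridged_cliques()
  set.seed(1)
  noise <- build_knn_graph(cbind(runif(6), runif(6)), 2)
  p1 <- leiden_multiplex(list(layer_spec(g, 1, 1)), seed = 5)
  p2 <- leiden_multiplex(list(layer_spec(g, 1, 1),
                              layer_spec(noise, 0, 1)), seed = 5)
  expect_identical(p1$membership, p2$membership)
})

test_that("scaling both layer weights leaves the partition unchanged", {
  for (seed in 1:5) {
    inst <- random_multiplex_instance(seed + 100)
    p1 <- leiden_multiplex(inst$layers, seed = 9)
    scaled <- lapply(inst$layers, function(l) {
      l$weight <- l$weight * 7.3
      l
    })
    p2 <- leiden_multiplex(scaled, seed = 9)
    expect_identical(p1$membership, p2$membership)
    expect_equal(p2$quality, 7.3 * p1$quality, tolerance = 1e-9)
  }
})

test_that("optimizer attains the exhaustive-enumeration optimum on small instances", {
  hits <- 0
  for (seed in 1:20) {
    inst <- random_multiplex_instance(seed + 500)
    p <- leiden_multiplex(inst$layers, seed = seed)
    opt <- oracle_multiplex_optimum(inst$adjs, inst$weights, inst$gammas)
    expect_lte(p$quality, opt + 1e-9)  # never exceeds the true optimum
    if (p$quality >= opt - 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("conflicting layers hand over as the spatial weight grows", {
  # expression layer: two 4-cliques {1..4}, {5..8}
  pairs1 <- cbind(t(combn(1:4, 2)), 1)
  pairs2 <- cbind(t(combn(5:8, 2)), 1)
  expr <- spot_graph(8, c(pairs1[, 1], pairs2[, 1]),
                     c(pairs1[, 2], pairs2[, 2]), weight = rep(1, 12))
  # spatial layer: conflicting pairing {1,2,5,6} vs {3,4,7,8}
  sp_pairs <- rbind(t(combn(c(1, 2, 5, 6), 2)), t(combn(c(3, 4, 7, 8), 2)))
  spat <- spot_graph(8, sp_pairs[, 1], sp_pairs[, 2], weight = rep(1, 12))
  lab_of <- function(w) {
    p <- leiden_multiplex(list(layer_spec(expr, 1, 1),
                               layer_spec(spat, w, 1)), seed = 2)
    p$membership
  }
  # extremes match the single-layer optima (confirmed exhaustively)
  expect_equal(oracle_multiplex_optimum(list(dense_adjacency(expr)), 1, 1),
               rb_quality(expr, rep(1:2, each = 4), 1))
  expect_equal(oracle_multiplex_optimum(list(dense_adjacency(spat)), 1, 1),
               rb_quality(spat, c(1, 1, 2, 2, 1, 1, 2, 2), 1))
  low <- lab_of(0)
  expect_equal(adjusted_rand_index(low, rep(1:2, each = 4)), 1)
  high <- lab_of(50)
  expect_equal(adjusted_rand_index(high, c(1, 1, 2, 2, 1, 1, 2, 2)), 1)
})

test_that("same seed reproduces the partition exactly", {
  set.seed(4)
  g1 <- build_knn_graph(matrix(rnorm(60), 30), 4)
  g2 <- build_knn_graph(cbind(runif(30), runif(30)), 3)
  layers <- list(layer_spec(g1, 1, 1), layer_spec(g2, 1, 1))
  p1 <- leiden_multiplex(layers, seed = 42)
  p2 <- leiden_multiplex(layers, seed = 42)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$quality_trace, p2$quality_trace)
  # quality trace is non-decreasing (asserted in-run as well)
  expect_true(all(diff(p1$quality_trace) > -1e-9))
})

test_that("final clusters are connected in the union of nonzero layers", {
  for (seed in 1:5) {
    inst <- random_multiplex_instance(seed + 900)
    p <- leiden_multiplex(inst$layers, seed = seed)
    U <- (inst$adjs[[1]] + inst$adjs[[2]]) > 0
    for (cl in unique(p$membership)) {
      nodes <- which(p$membership == cl)
      if (length(nodes) == 1) next
      # BFS within the cluster
      seen <- nodes[1]
      repeat {
        nxt <- which(colSums(U[seen, , drop = FALSE]) > 0)
        nxt <- intersect(setdiff(nxt, seen), nodes)
        if (!length(nxt)) break
        seen <- c(seen, nxt)
      }
      expect_setequal(seen, nodes)
    }
  }
})

test_that("resolution search follows the step/halve contract", {
  # stub: k = 2 below 0.5, else 3
  stub <- function(r) list(n_clusters = if (r < 0.5) 2 else 3)
  res <- search_resolution(stub, 3, r_init = 0.1, r_step = 0.1)
  expect_true(res$converged)
  expect_gte(res$resolution, 0.5)
  expect_equal(res$n_clusters, 3)
  # already at target: single evaluation
  res2 <- search_resolution(function(r) list(n_clusters = 4), 4, r_init = 1)
  expect_equal(res2$iterations, 1)
  expect_equal(res2$resolution, 1)
  # unreachable target returns closest with warning
  expect_warning(res3 <- search_resolution(stub, 7, max_iter = 10),
                 "closest")
  expect_equal(res3$n_clusters, 3)
})

test_that("spatialleiden validates inputs and reduces at weight zero", {
  set.seed(6)
  lat <- build_knn_graph(matrix(rnorm(80), 40), 5)
  spa <- build_knn_graph(cbind(runif(40), runif(40)), 4)
  fit <- suppressWarnings(
    spatialleiden(lat, spa, spatial_weight = 0, target_k = 3, seed = 11))
  direct <- suppressWarnings(search_resolution(function(r)
    leiden_multiplex(list(layer_spec(lat, 1, r)), seed = 11), 3))
  expect_identical(fit$membership, direct$partition$membership)
  expect_true(is.na(fit$resolutions["spatial"]))
  small <- build_knn_graph(cbind(runif(10), runif(10)), 2)
  expect_error(spatialleiden(lat, small, 1, target_k = 3, seed = 1),
               "nodes")
  expect_error(spatialleiden(lat, spa, -1, target_k = 3, seed = 1),
               "spatial_weight")
})
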