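square_lattice <- function(nr, nc) {
  spot_coordinates(sprintf("s%d", seq_len(nr * nc)),
                   rep(seq_len(nc), times = nr),
                   rep(seq_len(nr), each = nc),
                   technology = "square_grid")
}

hex_lattice <- function(nr, nc) {
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  spot_coordinates(sprintf("s%d", seq_len(nr * nc)),
                   cols + 0.5 * (rows %% 2), rows * sqrt(3) / 2,
                   technology = "hex_grid")
}

test_that("square lattice graph has degree 4 interior, 2 at corners", {
  g <- build_grid_graph(square_lattice(5, 5))
  deg <- graph_degree(g, weighted = FALSE)
  co <- square_lattice(5, 5)
  interior <- co$x > 1 & co$x < 5 & co$y > 1 & co$y < 5
  expect_true(all(deg[interior] == 4))
  corners <- (co$x %in% c(1, 5)) & (co$y %in% c(1, 5))
  expect_true(all(deg[corners] == 2))
  expect_true(all(g$edges$weight == 1))
})

test_that("hex lattice graph has degree 6 away from the boundary", {
  co <- hex_lattice(6, 6)
  g <- build_grid_graph(co)
  deg <- graph_degree(g, weighted = FALSE)
  interior <- co$y > min(co$y) + 0.1 & co$y < max(co$y) - 0.1 &
    co$x > min(co$x) + 1.1 & co$x < max(co$x) - 1.1
  expect_true(any(interior))
  expect_true(all(deg[interior] == 6))
})

test_that("single spot yields an empty grid graph; non-lattice input errors", {
  g <- build_grid_graph(spot_coordinates("a", 0, 0, technology = "square_grid"))
  expect_equal(nrow(g$edges), 0)
  set.seed(1)
  scattered <- spot_coordinates(sprintf("s%d", 1:40), runif(40), runif(40))
  expect_error(build_grid_graph(scattered, "square"), "lattice")
})

test_that("kNN graph matches the worked examples", {
  # two points, k = 1: one edge with their distance
  g <- build_knn_graph(cbind(c(0, 3), c(0, 4)), 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$distance, 5)
  # collinear 0,1,2,10 with k = 1: union symmetrization keeps 2-10
  g2 <- build_knn_graph(cbind(c(0, 1, 2, 10), 0), 1)
  expect_setequal(edge_set(g2), c("1 2", "2 3", "3 4"))
  # k >= n clips to the complete graph
  expect_warning(g3 <- build_knn_graph(cbind(1:5, 0), 10), "clipping")
  expect_equal(nrow(g3$edges), 10)
})

test_that("kNN graph agrees with a brute-force all-pairs oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(50:500, 1)
    k <- sample(3:8, 1)
    pts <- cbind(runif(n), runif(n))
    g <- build_knn_graph(pts, k)
    D <- as.matrix(dist(pts))
    diag(D) <- Inf
    expected <- character()
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[seq_len(k)]
      expected <- c(expected, paste(pmin(i, nb), pmax(i, nb)))
    }
    expect_setequal(edge_set(g), unique(expected))
    expect_true(all(graph_degree(g, weighted = FALSE) >= min(k, n - 1)))
  }
})

test_that("Delaunay handles the worked examples", {
  g <- build_delaunay_graph(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(g$edges), 3)
  # unit square: 4 sides + 1 diagonal
  g2 <- build_delaunay_graph(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(nrow(g2$edges), 5)
  expect_error(build_delaunay_graph(cbind(c(0, 1, 2), c(0, 1, 2))),
               "collinear")
  expect_error(build_delaunay_graph(cbind(c(0, 0, 1), c(0, 0, 1))),
               "duplicate")
})

test_that("Delaunay agrees with the empty-circumcircle oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:25, 1)
    pts <- cbind(runif(n), runif(n))
    g <- build_delaunay_graph(pts)
    expect_setequal(edge_set(g),
                    apply(oracle_delaunay_edges(pts), 1, paste, collapse = " "))
  }
})

test_that("distance transform follows 1 - d/d_max and drops zero weights", {
  g <- spot_graph(3, c(1, 2), c(2, 3), weight = c(1, 1), distance = c(2, 8))
  ct <- distances_to_connectivities(g)
  expect_equal(nrow(ct$edges), 1)  # the d = d_max edge is dropped
  expect_equal(ct$edges$weight, 0.75)
  g3 <- spot_graph(4, c(1, 2, 3), c(2, 3, 4), weight = rep(1, 3),
                   distance = c(4, 2, 8))
  ct3 <- distances_to_connectivities(g3)
  expect_equal(ct3$edges$weight[ct3$edges$from == 1], 0.5)
  # all-equal distances degenerate to an error
  ge <- spot_graph(3, c(1, 2), c(2, 3), weight = c(1, 1), distance = c(3, 3))
  expect_error(distances_to_connectivities(ge), "degenerate")
})

test_that("distance transform is scale invariant", {
  set.seed(42)
  g <- build_knn_graph(cbind(runif(30), runif(30)), 3)
  ct1 <- distances_to_connectivities(g)
  g2 <- g
  g2$edges$distance <- g2$edges$distance * 17.3
  ct2 <- distances_to_connectivities(g2)
  expect_equal(ct1$edges$weight, ct2$edges$weight, tolerance = 1e-12)
})

test_that("latent kNN kernel weights behave at the limits", {
  # identical latent vectors: all weights 1
  lat <- matrix(1, 6, 3)
  g <- build_latent_knn(lat, k = 2)
  expect_true(all(g$edges$weight == 1))
  # two well-separated blobs with small k: no cross-blob edges
  set.seed(3)
  blob <- rbind(matrix(rnorm(20 * 2, 0, 0.1), ncol = 2),
                matrix(rnorm(20 * 2, 100, 0.1), ncol = 2))
  g2 <- build_latent_knn(blob, k = 5)
  cross <- (g2$edges$from <= 20) != (g2$edges$to <= 20)
  expect_false(any(cross))
  expect_true(all(g2$edges$weight > 0 & g2$edges$weight <= 1))
  expect_error(build_latent_knn(matrix(c(1, NA), 2, 1), 1), "NaN")
})

test_that("graph builders are permutation equivariant", {
  set.seed(11)
  n <- 40
  pts <- cbind(runif(n), runif(n))
  perm <- sample(n)
  relabel <- function(g, map) paste(pmin(map[g$edges$from], map[g$edges$to]),
                                    pmax(map[g$edges$from], map[g$edges$to]))
  g1 <- build_knn_graph(pts, 4)
  g2 <- build_knn_graph(pts[perm, , drop = FALSE], 4)
  expect_setequal(edge_set(g1), relabel(g2, perm))
  d1 <- build_delaunay_graph(pts)
  d2 <- build_delaunay_graph(pts[perm, , drop = FALSE])
  expect_setequal(edge_set(d1), relabel(d2, perm))
})

test_that("edge-list TSV round-trips a graph", {
  dir <- withr::local_tempdir()
  set.seed(5)
  g <- build_knn_graph(cbind(runif(20), runif(20)), 3)
  path <- file.path(dir, "g.tsv")
  write_graph(g, path)
  back <- read_graph(path, 20)
  expect_equal(back$edges, g$edges, tolerance = 1e-12)
})
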