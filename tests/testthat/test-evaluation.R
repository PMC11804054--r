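test_that("ARI reproduces hand-derived cases and symmetry", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  a <- sample(1:4, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
})

test_that("ARI and NMI match independent implementations on random pairs", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(20:1000, 1)
    a <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    b <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    if (n <= 200) {
      expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                   tolerance = 1e-12)
      expect_equal(normalized_mutual_information(a, b), oracle_nmi(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("ARI of shuffled labels is centered at zero", {
  set.seed(99)
  a <- sample(1:5, 400, replace = TRUE)
  aris <- vapply(1:100, function(i) adjusted_rand_index(a, sample(a)),
                 numeric(1))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("NMI handles label permutation and degenerate partitions", {
  a <- sample(1:4, 100, replace = TRUE)
  relabeled <- c(4, 1, 3, 2)[a]
  expect_equal(normalized_mutual_information(a, relabeled), 1)
  expect_equal(normalized_mutual_information(rep(1, 10), rep(1, 10)), 1)
  expect_equal(normalized_mutual_information(rep(1, 10), rep(1:2, 5)), 0)
  # independent labels: NMI near zero at large n
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    normalized_mutual_information(sample(1:5, 10000, replace = TRUE),
                                  sample(1:5, 10000, replace = TRUE))
  }, numeric(1))
  expect_true(all(vals < 0.01))
})

test_that("labelings align by id with exclusion of unshared spots", {
  pred <- data.frame(id = c("a", "b", "c", "d"), label = c(1, 1, 2, 2))
  truth <- data.frame(id = c("b", "a", "c", "e"), label = c("u", "u", "v", "w"))
  expect_message(m <- evaluate_partition(pred, truth), "excluded")
  expect_equal(m$n_used, 3)
  expect_equal(m$n_excluded, 2)
  expect_equal(m$ari, 1)
})

test_that("exact Wilcoxon matches the sign-enumeration oracle", {
  # all-positive distinct differences: p = 2/32
  res <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 4.5))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$method, "exact")
  # balanced antisymmetric differences: p = 1
  res2 <- wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(res2$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:12, 1)
    x <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle_wilcoxon(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation tracks the reference test", {
  set.seed(5)
  x <- rnorm(60); y <- rnorm(60, 0.3)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$method, "normal approximation")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  # tie-free exact regime agrees with the reference exact test
  x2 <- rnorm(15); y2 <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x2, y2)$p_value,
               stats::wilcox.test(x2, y2, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(8)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  # direct step-up oracle
  o <- order(p)
  m <- length(p)
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  expect_equal(q[o], pmin(qs, 1), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("method comparison pairs samples and corrects across tests", {
  set.seed(31)
  tab <- data.frame(sample = rep(sprintf("s%02d", 1:12), 3),
                    method = rep(c("a", "b", "c"), each = 12),
                    ari = c(runif(12)))
  tab$ari[tab$method == "b"] <- tab$ari[tab$method == "a"] + 0.1
  tab$ari[tab$method == "c"] <- rev(tab$ari[tab$method == "a"])
  res <- compare_methods(tab, "a", "b")
  expect_equal(res$p, 2 / 4096, tolerance = 1e-12)
  expect_equal(res$q, res$p)  # single comparison
  all_pairs <- compare_methods(tab)
  expect_equal(nrow(all_pairs), 3)
  expect_true(all(all_pairs$q >= all_pairs$p))
  # identical methods surface as an explicit error
  tab2 <- tab
  tab2$ari[tab2$method == "b"] <- tab2$ari[tab2$method == "a"]
  expect_error(compare_methods(tab2, "a", "b"), "identical methods")
  expect_error(compare_methods(tab[tab$sample %in% c("s01", "s02"), ],
                               "a", "b"), "fewer than 3")
})
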