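align_labels <- function(a, b) {
  # accept plain vectors (positionally aligned) or (id, label) data.frames
  if (is.data.frame(a) && is.data.frame(b)) {
    shared <- intersect(a$id, b$id)
    excluded <- length(union(a$id, b$id)) - length(shared)
    if (excluded > 0)
      message(sprintf("%d spot(s) absent from one labeling excluded", excluded))
    if (length(shared) < 2) stop_sm("fewer than 2 shared spots")
    list(a = a$label[match(shared, a$id)], b = b$label[match(shared, b$id)],
         n_excluded = excluded)
  } else {
    if (length(a) != length(b))
      stop_sm("label vectors differ in length (%d vs %d)", length(a), length(b))
    if (length(a) < 2) stop_sm("need at least 2 spots")
    list(a = a, b = b, n_excluded = 0L)
  }
}

#' Adjusted Rand Index
#'
#' Chance-corrected pair-counting agreement between two partitions:
#' `ARI = (Index - E[Index]) / (Max - E[Index])` computed from the
#' contingency table. 1 for identical partitions, about 0 for independent
#' ones; can be negative.
#'
#' @param a,b label vectors (positionally aligned) or data.frames with
#'   columns `id`, `label` (aligned by id; spots missing from either side
#'   are excluded with a message).
#' @return The scalar index.
#' @export
adjusted_rand_index <- function(a, b) {
  al <- align_labels(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial (all-one-cluster or all-singletons)
  (sum_ij - expected) / (maxi - expected)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized Mutual Information
#'
#' `NMI = I(a;b) / normalizer(H(a), H(b))` with the arithmetic mean as
#' the default normalizer; in `[0, 1]`, and 1 exactly when the two
#' partitions are identical up to a label permutation. If both partitions
#' have a single cluster the NMI is defined as 1; if only one does, 0.
#'
#' @inheritParams adjusted_rand_index
#' @param normalization one of `"arithmetic"` (default), `"geometric"`,
#'   `"min"`, `"max"`.
#' @return The scalar score.
#' @export
normalized_mutual_information <- function(a, b,
    normalization = c("arithmetic", "geometric", "min", "max")) {
  normalization <- match.arg(normalization)
  al <- align_labels(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ha <- entropy_nats(pj)
  hb <- entropy_nats(pk)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pjk <- tab / n
  mask <- pjk > 0
  mi <- sum(pjk[mask] * log(pjk[mask] / (pj[row(tab)[mask]] * pk[col(tab)[mask]])))
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  min = min(ha, hb),
                  max = max(ha, hb))
  min(max(mi / denom, 0), 1)
}

# exact null distribution of the positive-rank sum W+ over 2^n equiprobable
# sign assignments, via convolution over doubled midranks (integers even
# under ties); returns P(W+ <= w) and P(W+ >= w)
signed_rank_tail <- function(ranks2, w2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1)  # index = value + 1
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / 2^length(ranks2)
  le <- sum(dist[seq_len(floor(w2 + 1e-9) + 1)])
  ge <- sum(dist[(ceiling(w2 - 1e-9) + 1):(total + 1)])
  c(le = le, ge = ge)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties in `|differences|` get midranks.
#' For n <= 25 retained pairs the two-sided p-value is exact, from the
#' full null distribution of the positive-rank sum over all `2^n` sign
#' assignments (computed by convolution, valid under ties); for larger n
#' a normal approximation with tie and continuity corrections is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit switch to the normal approximation above this
#'   number of nonzero differences (default 25).
#' @return list(statistic = positive-rank sum, n = pairs used, p_value,
#'   method).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) stop_sm("x and y must have equal length")
  d <- x - y
  if (anyNA(d)) stop_sm("NA in differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_sm("all differences are zero; test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    tails <- signed_rank_tail(as.integer(round(2 * r)), 2 * w)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, n = n, p_value = p, method = method)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} p_(j) m / j`, clipped
#' at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_sm("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Paired comparison of clustering methods across samples
#'
#' Runs two-sided Wilcoxon signed-rank tests on per-sample metric values
#' between methods and applies Benjamini-Hochberg correction across all
#' comparisons performed in the call.
#'
#' @param results data.frame with columns `sample`, `method` and the
#'   metric column named by `metric`.
#' @param method_a,method_b methods to compare; if omitted, all method
#'   pairs are compared.
#' @param metric name of the metric column (default `"ari"`).
#' @return data.frame with columns `method_a`, `method_b`, `n`,
#'   `statistic`, `p`, `q`.
#' @export
compare_methods <- function(results, method_a = NULL, method_b = NULL,
                            metric = "ari") {
  need <- c("sample", "method", metric)
  if (!all(need %in% names(results)))
    stop_sm("results must have columns %s", paste(need, collapse = ", "))
  methods_all <- unique(results$method)
  pairs <- if (!is.null(method_a) && !is.null(method_b)) {
    matrix(c(method_a, method_b), ncol = 2)
  } else {
    t(utils::combn(methods_all, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ma <- pairs[i, 1]; mb <- pairs[i, 2]
    xa <- results[results$method == ma, c("sample", metric)]
    xb <- results[results$method == mb, c("sample", metric)]
    shared <- intersect(xa$sample, xb$sample)
    if (length(shared) < 3)
      stop_sm("fewer than 3 shared samples for %s vs %s", ma, mb)
    va <- xa[[metric]][match(shared, xa$sample)]
    vb <- xb[[metric]][match(shared, xb$sample)]
    if (all(va == vb))
      stop_sm("identical methods: %s and %s have equal %s on every sample",
              ma, mb, metric)
    t <- wilcoxon_signed_rank(va, vb)
    data.frame(method_a = ma, method_b = mb, n = length(shared),
               statistic = t$statistic, p = t$p_value)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out
}

#' Evaluate a predicted partition against ground truth
#'
#' @param pred,truth data.frames with columns `id`, `label` (or `cluster`).
#' @return list(ari, nmi, n_used, n_excluded).
#' @export
evaluate_partition <- function(pred, truth) {
  fix <- function(df) {
    if ("cluster" %in% names(df) && !"label" %in% names(df))
      names(df)[names(df) == "cluster"] <- "label"
    df
  }
  pred <- fix(pred); truth <- fix(truth)
  al <- align_labels(pred, truth)
  list(ari = adjusted_rand_index(al$a, al$b),
       nmi = normalized_mutual_information(al$a, al$b),
       n_used = length(al$a), n_excluded = al$n_excluded)
}
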