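#' Moran's I spatial autocorrelation
#'
#' Computes `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = values - mean(values)` and `S0` the sum of all weights over
#' ordered pairs. Positive values indicate spatially smooth signals,
#' negative values alternating patterns; under spatial randomness the
#' expectation is `-1 / (n - 1)`.
#'
#' @param values numeric vector, one value per node; must not be constant.
#' @param g a [spot_graph] with at least one edge.
#' @param row_normalize row-normalize the weight matrix before scoring
#'   (the usual autocorrelation convention; default `TRUE`). Set `FALSE`
#'   to use the raw connectivity weights.
#' @return The scalar statistic.
#' @export
morans_i <- function(values, g, row_normalize = TRUE) {
  stopifnot(inherits(g, "spot_graph"))
  if (!nrow(g$edges)) stop_sm("graph has no edges")
  values <- as.numeric(values)
  if (length(values) != g$n) stop_sm("values length %d != %d nodes", length(values), g$n)
  if (anyNA(values) || any(!is.finite(values))) stop_sm("non-finite values")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop_sm("Moran's I undefined for constant values")
  W <- adjacency_matrix(g, row_normalize = row_normalize)
  s0 <- sum(W)
  as.numeric(g$n / s0 * (z %*% (W %*% z)) / ss)
}

# Moran's I for every column of a (possibly sparse) matrix at once.
morans_i_matrix <- function(M, g, row_normalize = TRUE) {
  W <- adjacency_matrix(g, row_normalize = row_normalize)
  s0 <- sum(W)
  n <- nrow(M)
  mu <- Matrix::colMeans(M)
  num <- den <- numeric(ncol(M))
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, ncol(M), by = block)) {
    cols <- start:min(start + block - 1L, ncol(M))
    Z <- as.matrix(M[, cols, drop = FALSE]) -
      matrix(mu[cols], n, length(cols), byrow = TRUE)
    num[cols] <- colSums(Z * as.matrix(W %*% Z))
    den[cols] <- colSums(Z^2)
  }
  I <- (n / s0) * num / den
  I[den == 0] <- NA_real_
  I
}

rank_genes <- function(ids, score, n_top) {
  ord <- order(-score, ids)  # ties broken lexicographically for reproducibility
  rank <- integer(length(ids)); rank[ord] <- seq_along(ids)
  n_sel <- min(n_top, sum(is.finite(score) & score > -Inf))
  selected <- rank <= n_sel & is.finite(score)
  data.frame(gene = ids, score = score, rank = rank, selected = selected,
             stringsAsFactors = FALSE)
}

#' Spatially variable gene selection by Moran's I
#'
#' Scores every gene by Moran's I on the spatial neighbor graph and
#' selects the `n_top` highest-scoring genes. Zero-variance genes score
#' `-Inf` and are never selected.
#'
#' @param x an [expression_matrix], conventionally log-normalized.
#' @param g the spatial [spot_graph].
#' @param n_top number of genes to select (default 3000); clipped to the
#'   number of genes with a warning.
#' @param row_normalize passed to the Moran's I weights.
#' @return A gene score table: data.frame with columns `gene`, `score`,
#'   `rank`, `selected`.
#' @export
select_svgs <- function(x, g, n_top = 3000, row_normalize = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is_count(n_top)) stop_sm("n_top must be a positive integer")
  p <- ncol(x$values)
  if (n_top > p) {
    warn_sm("n_top = %d > %d genes; selecting all", n_top, p)
    n_top <- p
  }
  I <- morans_i_matrix(x$values, g, row_normalize = row_normalize)
  I[is.na(I)] <- -Inf
  rank_genes(gene_ids(x), I, n_top)
}

#' Highly variable gene selection (variance-stabilized ranking)
#'
#' Ranks genes by the variance of clipped standardized counts: a local
#' regression (span 0.3) of `log10(variance)` on `log10(mean)` across
#' genes provides an expected standard deviation per gene; counts are
#' standardized by it, clipped at `sqrt(n_spots)`, and the variance of
#' the clipped values is the score.
#'
#' @param x an [expression_matrix] with raw counts.
#' @param n_top number of genes to select (default 3000).
#' @param span loess span for the mean-variance trend.
#' @return A gene score table (see [select_svgs()]).
#' @export
select_hvgs <- function(x, n_top = 3000, span = 0.3) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer_tag != "raw")
    stop_sm("select_hvgs expects raw counts but layer_tag is '%s'", x$layer_tag)
  if (!is_count(n_top)) stop_sm("n_top must be a positive integer")
  M <- x$values
  n <- nrow(M); p <- ncol(M)
  if (n_top > p) {
    warn_sm("n_top = %d > %d genes; selecting all", n_top, p)
    n_top <- p
  }
  mu <- as.numeric(Matrix::colMeans(M))
  ex2 <- as.numeric(Matrix::colMeans(M^2))
  v <- (ex2 - mu^2) * n / (n - 1)
  pos <- v > 0 & mu > 0
  if (sum(pos) < 10)
    stop_sm("only %d genes with nonzero variance; trend fit unstable", sum(pos))
  fit <- stats::loess(lv ~ lm, data = data.frame(lm = log10(mu[pos]), lv = log10(v[pos])),
                      span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  sd_fit <- numeric(p)
  sd_fit[pos] <- sqrt(10^stats::predict(fit, data.frame(lm = log10(mu[pos]))))
  clip <- sqrt(n)
  score <- numeric(p)
  block <- max(1L, floor(2e7 / n))
  for (start in seq(1L, p, by = block)) {
    cols <- start:min(start + block - 1L, p)
    Z <- as.matrix(M[, cols, drop = FALSE])
    ok <- pos[cols] & sd_fit[cols] > 0
    Z <- sweep(Z, 2, mu[cols], "-")
    Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, sd_fit[cols][ok], "/")
    Z <- pmin(Z, clip)
    sc <- colSums(sweep(Z, 2, colMeans(Z), "-")^2) / (n - 1)
    sc[!ok] <- 0
    score[cols] <- sc
  }
  rank_genes(gene_ids(x), score, n_top)
}

#' Subset an expression matrix to the selected genes of a score table
#'
#' @param x an [expression_matrix].
#' @param table a gene score table from [select_svgs()]/[select_hvgs()].
#' @return The [expression_matrix] restricted to selected genes, in rank
#'   order.
#' @export
subset_selected <- function(x, table) {
  sel <- table$gene[table$selected][order(table$rank[table$selected])]
  expression_matrix(x$values[, sel, drop = FALSE], layer_tag = x$layer_tag)
}

#' @rdname select_svgs
#' @param table a gene score table.
#' @param path output TSV path.
#' @export
write_gene_scores <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
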