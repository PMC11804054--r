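#' Spatially weighted principal component analysis (MULTISPATI-PCA)
#'
#' Fits either a standard PCA or its spatially weighted extension. For the
#' spatial fit the decomposition solves the symmetric eigenproblem of
#' `H = Xc' (W + W') Xc / (2n)`, where `Xc` is the column-centered data
#' and `W` the row-normalized spatial weight matrix built from `graph`.
#' Each eigenvalue factorizes as the product of the score variance and the
#' score's Moran's I, so the leading components trade variance against
#' spatial autocorrelation. With `graph = NULL` (or `W` the identity) the
#' fit reduces to PCA of the covariance `Xc'Xc / n`.
#'
#' Only the components with the largest (positive-side) eigenvalues are
#' kept by default; `n_neg` additionally keeps the most negatively
#' autocorrelated components. `H` is assembled with implicit centering
#' (no dense `n x p` intermediate), so sparse inputs stay sparse.
#'
#' @param x an [expression_matrix] (any layer).
#' @param graph spatial [spot_graph], or `NULL` for standard PCA.
#' @param n_comp number of components (default 30).
#' @param n_neg number of extra components from the negative end of the
#'   spectrum (default 0).
#' @param scale. standardize genes to unit variance before the fit
#'   (default `FALSE`; genes are always centered).
#' @param row_normalize row-normalize `W` (default `TRUE`); `FALSE` uses
#'   the raw connectivities.
#' @return An object of class `multispati` with elements `eigenvalues`,
#'   `loadings` (p x k, orthonormal), `scores` (n x k), `center`, `scale`,
#'   `W` (the weight matrix used, or `NULL` for PCA) and `call`.
#' @export
multispati <- function(x, graph = NULL, n_comp = 30, n_neg = 0,
                       scale. = FALSE, row_normalize = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  M <- x$values
  n <- nrow(M); p <- ncol(M)
  if (!is_count(n_comp)) stop_sm("n_comp must be a positive integer")
  if (n_comp + n_neg > min(n, p))
    stop_sm("n_comp + n_neg = %d exceeds min(n_spots, n_genes) = %d",
            n_comp + n_neg, min(n, p))
  mu <- as.numeric(Matrix::colMeans(M))
  scl <- rep(1, p)
  if (scale.) {
    v <- as.numeric(Matrix::colMeans(M^2)) - mu^2
    scl <- sqrt(v)
    scl[scl == 0] <- 1
  }
  W <- NULL
  if (is.null(graph)) {
    # H = Xc'Xc / n with implicit centering
    H <- (as.matrix(Matrix::crossprod(M)) - n * tcrossprod(mu)) / n
  } else {
    stopifnot(inherits(graph, "spot_graph"))
    if (graph$n != n) stop_sm("graph has %d nodes but matrix has %d spots", graph$n, n)
    if (!nrow(graph$edges)) stop_sm("spatial graph has no edges")
    deg <- graph_degree(graph)
    if (any(deg == 0))
      warn_sm("%d isolated node(s); their weight-matrix rows are zero", sum(deg == 0))
    W <- adjacency_matrix(graph, row_normalize = row_normalize)
    S <- (W + Matrix::t(W)) / 2
    # Xc' S Xc = X'SX - mu r' - r mu' + (1'S1) mu mu', r = X'S1
    XtSX <- as.matrix(Matrix::crossprod(M, S %*% M))
    r <- as.numeric(Matrix::crossprod(M, S %*% rep(1, n)))
    s11 <- sum(S)
    H <- (XtSX - tcrossprod(mu, r) - tcrossprod(r, mu) + s11 * tcrossprod(mu)) / n
  }
  if (scale.) H <- H / tcrossprod(scl)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  take <- seq_len(n_comp)
  if (n_neg > 0) take <- c(take, p - rev(seq_len(n_neg)) + 1L)
  vals <- ev$values[take]
  U <- ev$vectors[, take, drop = FALSE]
  # canonical sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  rownames(U) <- gene_ids(x)
  colnames(U) <- sprintf("C%d", seq_len(ncol(U)))
  Xs <- Matrix::t((Matrix::t(M) - mu) / scl)
  scores <- as.matrix(Xs %*% U)
  rownames(scores) <- spot_ids(x)
  structure(list(eigenvalues = vals, loadings = U, scores = scores,
                 center = stats::setNames(mu, gene_ids(x)),
                 scale = if (scale.) scl else NULL,
                 W = W, n = n, mode = if (is.null(graph)) "pca" else "multispati",
                 call = match.call()),
            class = "multispati")
}

#' @rdname multispati
#' @export
fit_pca <- function(x, n_comp = 30, scale. = FALSE) {
  multispati(x, graph = NULL, n_comp = n_comp, scale. = scale.)
}

#' @export
print.multispati <- function(x, ...) {
  cat(sprintf("%s fit: %d components over %d genes, %d spots\n",
              if (x$mode == "pca") "PCA" else "MULTISPATI-PCA",
              length(x$eigenvalues), nrow(x$loadings), x$n))
  cat("eigenvalues:", format(utils::head(x$eigenvalues, 8), digits = 4),
      if (length(x$eigenvalues) > 8) "..." else "", "\n")
  invisible(x)
}

#' Project new data onto a fitted decomposition
#'
#' @param object a fitted [multispati] model.
#' @param newdata an [expression_matrix] with the same genes, in the same
#'   order, as the fit.
#' @param ... unused.
#' @return The score matrix `(X - center) %*% loadings`.
#' @export
predict.multispati <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$scores)
  stopifnot(inherits(newdata, "expression_matrix"))
  if (!identical(gene_ids(newdata), rownames(object$loadings)))
    stop_sm("gene set/order of newdata does not match the fitted model")
  scl <- object$scale %||% rep(1, length(object$center))
  Xs <- Matrix::t((Matrix::t(newdata$values) - object$center) / scl)
  out <- as.matrix(Xs %*% object$loadings)
  rownames(out) <- spot_ids(newdata)
  out
}

#' Eigenvalue decomposition table
#'
#' Per component, the variance of the scores and their Moran's I under the
#' weight matrix used at fit time; their product reproduces the eigenvalue
#' (a defining identity of the spatially weighted decomposition). For a
#' plain PCA fit, Moran's I requires `graph`.
#'
#' @param model a fitted [multispati] model.
#' @param graph optional [spot_graph] for scoring a PCA fit.
#' @param row_normalize matches the fit's weight convention.
#' @return data.frame with columns `component`, `eigenvalue`, `variance`,
#'   `morans_i`, `product`.
#' @export
eigenvalue_table <- function(model, graph = NULL, row_normalize = TRUE) {
  stopifnot(inherits(model, "multispati"))
  n <- model$n
  vr <- colSums(sweep(model$scores, 2, colMeans(model$scores), "-")^2) / n
  if (!is.null(model$W)) {
    W <- model$W
  } else if (!is.null(graph)) {
    W <- adjacency_matrix(graph, row_normalize = row_normalize)
  } else {
    W <- NULL
  }
  I <- rep(NA_real_, ncol(model$scores))
  if (!is.null(W)) {
    s0 <- sum(W)
    for (j in seq_len(ncol(model$scores))) {
      z <- model$scores[, j] - mean(model$scores[, j])
      I[j] <- n / s0 * as.numeric(z %*% (W %*% z)) / sum(z^2)
    }
  }
  data.frame(component = colnames(model$scores),
             eigenvalue = model$eigenvalues,
             variance = vr, morans_i = I, product = vr * I)
}

#' @export
summary.multispati <- function(object, ...) {
  tab <- eigenvalue_table(object)
  structure(list(table = tab, mode = object$mode), class = "summary.multispati")
}

#' @export
print.summary.multispati <- function(x, ...) {
  cat(sprintf("%s components (eigenvalue = variance x Moran's I):\n",
              if (x$mode == "pca") "PCA" else "MULTISPATI-PCA"))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.multispati <- function(x, ...) {
  tab <- eigenvalue_table(x)
  if (all(is.na(tab$morans_i))) {
    graphics::barplot(tab$eigenvalue, names.arg = tab$component,
                      ylab = "eigenvalue", las = 2, ...)
  } else {
    graphics::plot(tab$variance, tab$morans_i,
                   xlab = "score variance", ylab = "Moran's I",
                   pch = 19, cex = 0.8, ...)
    graphics::text(tab$variance, tab$morans_i, tab$component,
                   pos = 3, cex = 0.6)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Write a fitted decomposition to a directory of TSV files
#'
#' Writes `eigenvalues.tsv`, `loadings.tsv`, `scores.tsv`, `center.tsv`
#' and a small JSON metadata file, a plain-text layout that round-trips
#' via [read_multispati()].
#'
#' @param model a fitted [multispati] model.
#' @param dir output directory.
#' @export
write_multispati <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(component = colnames(model$scores),
                                eigenvalue = model$eigenvalues),
                     file.path(dir, "eigenvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(model$loadings), model$loadings),
                     file.path(dir, "loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(model$scores), model$scores),
                     file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(model$center),
                                center = model$center,
                                scale = model$scale %||% rep(1, length(model$center))),
                     file.path(dir, "center.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(mode = model$mode, n = model$n,
                            scaled = !is.null(model$scale)),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_multispati
#' @export
read_multispati <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  evs <- utils::read.table(file.path(dir, "eigenvalues.tsv"), sep = "\t", header = TRUE)
  ld <- utils::read.table(file.path(dir, "loadings.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  sc <- utils::read.table(file.path(dir, "scores.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  ce <- utils::read.table(file.path(dir, "center.tsv"), sep = "\t", header = TRUE)
  loadings <- as.matrix(ld[, -1, drop = FALSE]); rownames(loadings) <- ld[[1]]
  scores <- as.matrix(sc[, -1, drop = FALSE]); rownames(scores) <- sc[[1]]
  structure(list(eigenvalues = evs$eigenvalue, loadings = loadings,
                 scores = scores,
                 center = stats::setNames(ce$center, ce$gene),
                 scale = if (isTRUE(meta$scaled)) ce$scale else NULL,
                 W = NULL, n = meta$n, mode = meta$mode, call = NULL),
            class = "multispati")
}
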