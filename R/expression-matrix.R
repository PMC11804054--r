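#' Spot-by-gene expression matrix
#'
#' Container for a spots x genes expression matrix with unique spot and
#' gene identifiers and a layer tag recording the processing state of the
#' values (`"raw"` counts, `"normalized"` or `"log"`). Values are held in a
#' sparse [Matrix::dgCMatrix-class] when given sparse input.
#'
#' @param values numeric matrix or sparse Matrix, spots in rows, genes in
#'   columns; non-negative for `layer_tag = "raw"`, never NaN/NA.
#' @param spot_ids,gene_ids character vectors of unique identifiers;
#'   default taken from `dimnames(values)`.
#' @param layer_tag one of `"raw"`, `"normalized"`, `"log"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (dimnames carry the ids) and `layer_tag`.
#' @export
expression_matrix <- function(values, spot_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer_tag = c("raw", "normalized", "log")) {
  layer_tag <- match.arg(layer_tag)
  if (is.null(spot_ids)) spot_ids <- sprintf("spot%d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(ncol(values)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (length(spot_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop_sm("id lengths (%d spots, %d genes) do not match matrix dimensions %d x %d",
            length(spot_ids), length(gene_ids), nrow(values), ncol(values))
  if (anyDuplicated(spot_ids))
    stop_sm("duplicate spot ids: %s",
            paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop_sm("duplicate gene ids: %s",
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- if (inherits(values, "sparseMatrix")) {
    methods::as(methods::as(values, "generalMatrix"), "CsparseMatrix")
  } else {
    as.matrix(values)
  }
  v <- if (inherits(vals, "sparseMatrix")) vals@x else vals
  if (anyNA(v) || any(is.nan(v))) stop_sm("expression values contain NA/NaN")
  if (layer_tag == "raw" && length(v) && min(v) < 0)
    stop_sm("negative entries in raw count matrix")
  dimnames(vals) <- list(spot_ids, gene_ids)
  structure(list(values = vals, layer_tag = layer_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d spots x %d genes [%s]%s\n",
              nrow(x$values), ncol(x$values), x$layer_tag,
              if (inherits(x$values, "sparseMatrix")) " (sparse)" else ""))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
spot_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) colnames(x$values)

read_id_file <- function(path) {
  ids <- readLines(path, encoding = "UTF-8")
  ids <- ids[nzchar(ids)]
  # tolerate a multi-column TSV (first column is the id)
  sub("\t.*$", "", ids)
}

#' Read an expression matrix from disk
#'
#' Reads a MatrixMarket coordinate file (`.mtx`) or a dense TSV together
#' with one-id-per-line spot and gene id files. The on-disk orientation is
#' spots x genes unless `transpose = TRUE`.
#'
#' @param path_matrix path to the `.mtx` or dense TSV matrix file.
#' @param path_spots,path_genes paths to id files, one id per line.
#' @param transpose logical; set when the matrix file is stored genes x
#'   spots.
#' @param layer_tag layer tag to assign, default `"raw"`.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path_matrix, path_spots, path_genes,
                            transpose = FALSE, layer_tag = "raw") {
  for (p in c(path_matrix, path_spots, path_genes))
    if (!file.exists(p)) stop_sm("file not found: %s", p)
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    m <- Matrix::readMM(path_matrix)
  } else {
    m <- as.matrix(utils::read.table(path_matrix, sep = "\t", header = FALSE))
    if (!is.numeric(m)) stop_sm("dense matrix file %s contains non-numeric entries", path_matrix)
    dimnames(m) <- NULL
  }
  if (transpose) m <- Matrix::t(m)
  spots <- read_id_file(path_spots)
  genes <- read_id_file(path_genes)
  if (nrow(m) != length(spots) || ncol(m) != length(genes))
    stop_sm("matrix is %d x %d but id files give %d spots and %d genes",
            nrow(m), ncol(m), length(spots), length(genes))
  expression_matrix(m, spots, genes, layer_tag = layer_tag)
}

#' Write an expression matrix to disk
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate), `spots.tsv` and
#' `genes.tsv` (one id per line) under `dir`. Round-trips through
#' [read_expression()] exactly for integer counts.
#'
#' @param x an [expression_matrix].
#' @param dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(x, dir) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "spots.tsv", "genes.tsv"))
  m <- x$values
  if (!inherits(m, "sparseMatrix")) m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, paths[1])
  writeLines(spot_ids(x), paths[2])
  writeLines(gene_ids(x), paths[3])
  invisible(paths)
}

#' Total-count normalization followed by log1p
#'
#' Scales each spot's counts to a common total, then applies
#' `log(1 + v)`. This is the conventional preprocessing between raw counts
#' and PCA in transcriptomics pipelines.
#'
#' @param x an [expression_matrix] with `layer_tag = "raw"`.
#' @param target_sum positive total each spot is scaled to (default 1e4).
#' @return An [expression_matrix] with `layer_tag = "log"`.
#' @export
normalize_log1p <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$layer_tag != "raw")
    stop_sm("normalize_log1p expects raw counts but layer_tag is '%s'", x$layer_tag)
  if (!(is.numeric(target_sum) && target_sum > 0)) stop_sm("target_sum must be positive")
  totals <- Matrix::rowSums(x$values)
  zero <- totals <= 0
  if (any(zero))
    stop_sm("spots with zero total count: %s",
            paste(spot_ids(x)[zero], collapse = ", "))
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% x$values
  out <- if (inherits(x$values, "sparseMatrix")) {
    s <- methods::as(scaled, "CsparseMatrix")
    s@x <- log1p(s@x)
    s
  } else {
    log1p(as.matrix(scaled))
  }
  dimnames(out) <- dimnames(x$values)
  expression_matrix(out, layer_tag = "log")
}
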