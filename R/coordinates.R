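#' Spot coordinates
#'
#' A table of 2-D physical coordinates, one row per spot, with a technology
#' tag controlling spatial-graph construction: `"hex_grid"` (e.g. Visium),
#' `"square_grid"` (e.g. binned Stereo-seq) or `"generic"` (imaging-based
#' platforms with irregular cell positions).
#'
#' @param id character spot ids, unique.
#' @param x,y numeric coordinates (same physical units per axis).
#' @param technology one of `"hex_grid"`, `"square_grid"`, `"generic"`.
#' @return A `spot_coordinates` data.frame with columns id, x, y and a
#'   `technology` attribute.
#' @export
spot_coordinates <- function(id, x, y,
                             technology = c("generic", "hex_grid", "square_grid")) {
  technology <- match.arg(technology)
  id <- as.character(id)
  if (anyDuplicated(id)) stop_sm("duplicate spot ids in coordinates")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(id) || length(y) != length(id))
    stop_sm("id, x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_sm("non-finite coordinates")
  if (technology != "generic" && anyDuplicated(cbind(x, y)))
    stop_sm("duplicate coordinates are not allowed for grid technologies")
  structure(data.frame(id = id, x = x, y = y, stringsAsFactors = FALSE),
            technology = technology,
            class = c("spot_coordinates", "data.frame"))
}

#' Read spot coordinates from a TSV file
#'
#' Expects a header line `id<TAB>x<TAB>y`; row order is preserved.
#'
#' @param path path to the TSV file.
#' @inheritParams spot_coordinates
#' @return A [spot_coordinates] table.
#' @export
read_coordinates <- function(path, technology = "generic") {
  if (!file.exists(path)) stop_sm("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", NA, NA),
                          check.names = FALSE, quote = "", comment.char = "")
  need <- c("id", "x", "y")
  if (!all(need %in% names(df)))
    stop_sm("coordinate file %s must have columns id, x, y (found: %s)",
            path, paste(names(df), collapse = ", "))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop_sm("non-numeric coordinates in %s", path)
  spot_coordinates(df$id, df$x, df$y, technology = technology)
}

#' @rdname read_coordinates
#' @param coords a [spot_coordinates] table.
#' @export
write_coordinates <- function(coords, path) {
  utils::write.table(coords[, c("id", "x", "y")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a label vector (spot id, label)
#'
#' Labels are categorical spot annotations: ground-truth domains or
#' cluster assignments. Files are TSV with a header and two columns.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `id` (character) and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_sm("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2) stop_sm("label file %s needs two columns (id, label)", path)
  out <- data.frame(id = df[[1]], label = df[[2]], stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) stop_sm("duplicate ids in label file %s", path)
  if (length(unique(out$label)) < 1) stop_sm("label file %s has no labels", path)
  out
}

#' @rdname read_labels
#' @param ids character spot ids.
#' @param labels labels aligned to `ids`.
#' @param colname name of the label column in the written file.
#' @export
write_labels <- function(ids, labels, path, colname = "label") {
  df <- data.frame(id = as.character(ids), label = labels)
  names(df)[2] <- colname
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
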