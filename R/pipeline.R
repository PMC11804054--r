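#' Run configuration
#'
#' Collects the tunable parameters of the full workflow with the standard
#' defaults: 3000 selected genes, 30 latent components, 15 latent
#' neighbors, 10 spatial neighbors (for generic coordinates).
#'
#' @param n_top_genes genes kept by feature selection.
#' @param n_components latent dimensions.
#' @param latent_k neighbors in the latent-space graph.
#' @param spatial_k neighbors in the spatial kNN graph (generic
#'   coordinates only).
#' @param spatial_weight weight of the spatial layer (latent layer is 1).
#' @param target_clusters desired number of domains.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param graph_mode `"grid"`, `"delaunay"` or `"knn"`.
#' @param feature_mode `"hvg"`, `"svg"` or `"all"`.
#' @param dimred_mode `"pca"` or `"multispati"`.
#' @param technology `"hex_grid"`, `"square_grid"` or `"generic"`.
#' @return A `run_config` list.
#' @export
run_config <- function(n_top_genes = 3000, n_components = 30, latent_k = 15,
                       spatial_k = 10, spatial_weight = 1,
                       target_clusters = 4, seed = 0,
                       graph_mode = c("grid", "delaunay", "knn"),
                       feature_mode = c("hvg", "svg", "all"),
                       dimred_mode = c("pca", "multispati"),
                       technology = c("generic", "hex_grid", "square_grid")) {
  graph_mode <- match.arg(graph_mode)
  feature_mode <- match.arg(feature_mode)
  dimred_mode <- match.arg(dimred_mode)
  technology <- match.arg(technology)
  for (nm in c("n_top_genes", "n_components", "latent_k", "spatial_k",
               "target_clusters"))
    if (!is_count(get(nm))) stop_sm("%s must be a positive integer", nm)
  if (!identical(spatial_weight, "match") &&
      (!is.numeric(spatial_weight) || spatial_weight < 0))
    stop_sm("spatial_weight must be >= 0 or \"match\"")
  structure(list(n_top_genes = n_top_genes, n_components = n_components,
                 latent_k = latent_k, spatial_k = spatial_k,
                 spatial_weight = spatial_weight,
                 target_clusters = target_clusters, seed = seed,
                 graph_mode = graph_mode, feature_mode = feature_mode,
                 dimred_mode = dimred_mode, technology = technology),
            class = "run_config")
}

#' Read a run configuration from a flat JSON file
#'
#' Keys mirror [run_config()] arguments; `overrides` (e.g. parsed CLI
#' flags) take precedence over file values.
#'
#' @param path JSON file, or `NULL` for defaults.
#' @param overrides named list of values overriding the file.
#' @return A `run_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full spatial-domain detection workflow
#'
#' Executes reading, normalization, feature selection, dimensionality
#' reduction, graph construction and two-stage spatially aware clustering
#' as configured, writing `clusters.tsv` and a `manifest.json` run report
#' to `out_dir`. Each stage draws its seed from the master seed via
#' [derive_seed()], so a rerun with the same config is byte-identical.
#'
#' @param config a [run_config].
#' @param path_matrix,path_spots,path_genes expression input (see
#'   [read_expression()]).
#' @param path_coords coordinate TSV (see [read_coordinates()]).
#' @param out_dir output directory.
#' @param path_truth optional ground-truth label TSV; when given, ARI/NMI
#'   are added to the manifest.
#' @param transpose passed to [read_expression()].
#' @param quiet suppress progress messages.
#' @return Invisibly, list(fit, manifest).
#' @export
run_pipeline <- function(config, path_matrix, path_spots, path_genes,
                         path_coords, out_dir, path_truth = NULL,
                         transpose = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  say <- function(stage, fmt, ...) {
    if (!quiet)
      message(sprintf("[%s] (seed %d) %s", stage,
                      derive_seed(config$seed, stage), sprintf(fmt, ...)))
  }
  tick <- function(stage, expr) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_sm("stage '%s' failed: %s", stage, conditionMessage(e)))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t1, 3)
    out
  }

  counts <- tick("read", read_expression(path_matrix, path_spots, path_genes,
                                         transpose = transpose))
  coords <- tick("read", read_coordinates(path_coords,
                                          technology = config$technology))
  if (!identical(spot_ids(counts), coords$id)) {
    if (!setequal(spot_ids(counts), coords$id))
      stop_sm("stage 'read' failed: spot ids of matrix and coordinates differ")
    coords <- coords[match(spot_ids(counts), coords$id), ]
  }
  say("read", "%d spots x %d genes", dim(counts)[1], dim(counts)[2])

  tissue <- list(counts = counts, coords = coords)
  pr <- tick("prepare", prepare_tissue(tissue,
                                       feature_mode = config$feature_mode,
                                       dimred_mode = config$dimred_mode,
                                       n_top = config$n_top_genes,
                                       n_comp = config$n_components,
                                       latent_k = config$latent_k,
                                       spatial_k = config$spatial_k,
                                       graph_mode = config$graph_mode,
                                       seed = config$seed))
  say("prepare", "%d genes selected, %d components",
      dim(pr$selected)[2], length(pr$model$eigenvalues))

  fit <- tick("cluster",
              spatialleiden(pr$latent_graph, pr$spatial_graph,
                            spatial_weight = config$spatial_weight,
                            target_k = config$target_clusters,
                            seed = derive_seed(config$seed, "cluster")))
  say("cluster", "%d clusters, quality %.3f", fit$n_clusters, fit$quality)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_tsv <- file.path(out_dir, "clusters.tsv")
  write_partition(fit, spot_ids(counts), out_tsv)

  metrics <- NULL
  if (!is.null(path_truth)) {
    truth <- tick("evaluate", read_labels(path_truth))
    metrics <- evaluate_partition(
      data.frame(id = spot_ids(counts), label = fit$membership), truth)
    say("evaluate", "ARI %.3f, NMI %.3f", metrics$ari, metrics$nmi)
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c("read", "prepare", "cluster")),
                         function(s) derive_seed(config$seed, s)),
    resolutions = as.list(fit$resolutions),
    n_clusters = fit$n_clusters,
    quality = fit$quality,
    quality_trace = fit$quality_trace,
    passes = fit$passes,
    converged = fit$converged,
    metrics = metrics,
    timings = timings,
    elapsed = round(proc.time()[["elapsed"]] - t0, 3),
    outputs = as.list(tools::md5sum(out_tsv))
  )
  # atomic manifest write
  tmp <- tempfile(tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(list(fit = fit, manifest = manifest))
}

#' Sweep the spatial-layer weight
#'
#' Convenience wrapper reproducing the weight-sensitivity diagnostic:
#' cluster at each weight and report ARI/NMI against a ground truth.
#'
#' @param latent_graph,spatial_graph the two layers.
#' @param weights numeric vector of spatial weights.
#' @param target_k desired cluster count.
#' @param truth data.frame(id, label).
#' @param ids spot ids aligned to the graphs.
#' @param seed clustering seed.
#' @return data.frame(weight, n_clusters, ari, nmi).
#' @export
sweep_weight <- function(latent_graph, spatial_graph, weights, target_k,
                         truth, ids, seed = 0) {
  rows <- lapply(weights, function(w) {
    fit <- spatialleiden(latent_graph, spatial_graph, spatial_weight = w,
                         target_k = target_k, seed = seed)
    m <- evaluate_partition(data.frame(id = ids, label = fit$membership),
                            truth)
    data.frame(weight = w, n_clusters = fit$n_clusters,
               ari = m$ari, nmi = m$nmi)
  })
  do.call(rbind, rows)
}
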