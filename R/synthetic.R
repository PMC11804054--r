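#' Specification of a synthetic tissue
#'
#' Parameters of the layered-tissue simulator used for end-to-end
#' validation. Defaults emulate a desk-scale capture-based section:
#' ~2000 spots on a square grid divided into 4 horizontal domain bands,
#' 500 genes of which 25 per domain are markers up-regulated by a log
#' fold change of 1, negative-binomial counts (dispersion `size = 2`,
#' ~2000 counts per spot), and 30% of spots carrying another domain's
#' expression profile (`noise_mixing = 0.3`) to mimic the ambiguous
#' border/mixed spots whose assignment spatial information resolves.
#'
#' @param layout `"square_grid"`, `"hex_grid"` or `"random_points"`.
#' @param n_spots number of spots.
#' @param n_domains number of spatial domains K (>= 2).
#' @param pattern `"layered_strips"` (horizontal bands) or `"voronoi"`
#'   (irregular patches around seeded centers).
#' @param n_genes total number of genes.
#' @param n_markers_per_domain marker genes per domain
#'   (`K * n_markers_per_domain <= n_genes`).
#' @param marker_log_fold_change natural-log fold change of markers in
#'   their own domain.
#' @param dispersion negative-binomial size parameter (variance
#'   `mu + mu^2/size`); `Inf` gives Poisson counts.
#' @param library_size expected total counts per spot.
#' @param noise_mixing probability in `[0, 1)` that a spot's expression
#'   is drawn from a uniformly random other domain's profile.
#' @param seed integer seed; the full simulation is deterministic in it.
#' @return A `tissue_spec` list.
#' @export
tissue_spec <- function(layout = c("square_grid", "hex_grid", "random_points"),
                        n_spots = 2000, n_domains = 4,
                        pattern = c("layered_strips", "voronoi"),
                        n_genes = 500, n_markers_per_domain = 25,
                        marker_log_fold_change = 1.0, dispersion = 2,
                        library_size = 2000, noise_mixing = 0.3, seed = 0) {
  layout <- match.arg(layout)
  pattern <- match.arg(pattern)
  if (n_domains < 2) stop_sm("need at least 2 domains")
  if (n_spots < n_domains) stop_sm("n_spots < n_domains")
  if (n_markers_per_domain * n_domains > n_genes)
    stop_sm("%d marker genes exceed n_genes = %d",
            n_markers_per_domain * n_domains, n_genes)
  if (noise_mixing < 0 || noise_mixing >= 1)
    stop_sm("noise_mixing must be in [0, 1)")
  if (!(dispersion > 0)) stop_sm("dispersion must be positive")
  structure(list(layout = layout, n_spots = n_spots, n_domains = n_domains,
                 pattern = pattern, n_genes = n_genes,
                 n_markers_per_domain = n_markers_per_domain,
                 marker_log_fold_change = marker_log_fold_change,
                 dispersion = dispersion, library_size = library_size,
                 noise_mixing = noise_mixing, seed = seed),
            class = "tissue_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Lay out spots and assign ground-truth domains
#'
#' Places spots according to `spec$layout` and labels them with spatially
#' contiguous domains: `layered_strips` cuts the section into K
#' horizontal bands of near-equal spot count; `voronoi` labels each spot
#' by its nearest of K seeded centers.
#'
#' @param spec a [tissue_spec].
#' @return list(coords = [spot_coordinates], truth = data.frame(id,
#'   label)).
#' @export
make_layout <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(derive_seed(spec$seed, "layout"), {
    n <- spec$n_spots
    if (spec$layout == "random_points") {
      side <- sqrt(n)
      x <- stats::runif(n, 0, side)
      y <- stats::runif(n, 0, side)
      tech <- "generic"
    } else {
      ncol_ <- ceiling(sqrt(n))
      nrow_ <- ceiling(n / ncol_)
      rows <- rep(seq_len(nrow_), each = ncol_)[seq_len(n)]
      cols <- rep(seq_len(ncol_), times = nrow_)[seq_len(n)]
      if (spec$layout == "hex_grid") {
        x <- cols + 0.5 * (rows %% 2)
        y <- rows * sqrt(3) / 2
        tech <- "hex_grid"
      } else {
        x <- as.numeric(cols)
        y <- as.numeric(rows)
        tech <- "square_grid"
      }
    }
    K <- spec$n_domains
    if (spec$pattern == "layered_strips") {
      # near-equal bands by y; whole rows stay together on grids
      ord <- order(y, x)
      lab <- integer(n)
      lab[ord] <- ceiling(seq_len(n) / (n / K))
      # keep equal-y rows in one band: assign each distinct y the band of
      # the majority of its members
      for (yy in unique(y)) {
        idx <- which(y == yy)
        if (length(idx) > 1) {
          tt <- table(lab[idx])
          lab[idx] <- as.integer(names(tt)[which.max(tt)])
        }
      }
      lab <- pmin(pmax(lab, 1L), K)
    } else {
      repeat {
        cx <- stats::runif(K, min(x), max(x))
        cy <- stats::runif(K, min(y), max(y))
        d2 <- outer(x, cx, function(a, b) (a - b)^2) +
          outer(y, cy, function(a, b) (a - b)^2)
        lab <- max.col(-d2)
        if (length(unique(lab)) == K) break
      }
    }
    ids <- sprintf("spot%04d", seq_len(n))
    list(coords = spot_coordinates(ids, x, y, technology = tech),
         truth = data.frame(id = ids, label = sprintf("domain%d", lab),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate domain-structured expression counts
#'
#' Baseline gene means are drawn log-normal and shared across domains;
#' each domain's marker genes are up-regulated by
#' `exp(marker_log_fold_change)`. Spot counts are negative binomial with
#' the domain profile scaled to the library size. With probability
#' `noise_mixing` a spot's counts are instead drawn from a uniformly
#' random other domain's profile, creating expression-ambiguous spots
#' that only spatial context can assign correctly.
#'
#' @param labels data.frame(id, label) from [make_layout()].
#' @param spec a [tissue_spec].
#' @return An [expression_matrix] of raw counts. The indices of mixed
#'   spots are attached as attribute `"mixed"`.
#' @export
simulate_expression <- function(labels, spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(derive_seed(spec$seed, "expression"), {
    n <- nrow(labels)
    K <- spec$n_domains
    p <- spec$n_genes
    dom <- as.integer(factor(labels$label,
                             levels = sort(unique(labels$label))))
    base <- stats::rlnorm(p, meanlog = 0, sdlog = 1)
    markers <- matrix(seq_len(spec$n_markers_per_domain * K),
                      nrow = spec$n_markers_per_domain)
    profiles <- matrix(base, nrow = K, ncol = p, byrow = TRUE)
    for (d in seq_len(K))
      profiles[d, markers[, d]] <- profiles[d, markers[, d]] *
        exp(spec$marker_log_fold_change)
    profiles <- profiles / rowSums(profiles)
    use_dom <- dom
    mixed <- which(stats::runif(n) < spec$noise_mixing)
    if (length(mixed)) {
      shift <- sample.int(K - 1, length(mixed), replace = TRUE)
      use_dom[mixed] <- 1L + (dom[mixed] - 1L + shift) %% K
    }
    mu <- profiles[use_dom, , drop = FALSE] * spec$library_size
    counts <- if (is.finite(spec$dispersion)) {
      matrix(stats::rnbinom(n * p, mu = mu, size = spec$dispersion), n, p)
    } else {
      matrix(stats::rpois(n * p, lambda = mu), n, p)
    }
    x <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE),
                           spot_ids = labels$id,
                           gene_ids = sprintf("gene%04d", seq_len(p)))
    attr(x, "mixed") <- mixed
    x
  })
}

#' Simulate a complete synthetic tissue
#'
#' @param spec a [tissue_spec].
#' @return list(counts = [expression_matrix], coords =
#'   [spot_coordinates], truth = data.frame(id, label)).
#' @export
simulate_tissue <- function(spec) {
  lay <- make_layout(spec)
  counts <- simulate_expression(lay$truth, spec)
  # guard against spots that drew zero total counts (pathological specs)
  totals <- Matrix::rowSums(counts$values)
  if (any(totals == 0)) {
    bump <- which(totals == 0)
    counts$values[cbind(bump, 1L)] <- 1
  }
  list(counts = counts, coords = lay$coords, truth = lay$truth)
}

#' Write a simulated tissue to a directory
#'
#' Writes `matrix.mtx`, `spots.tsv`, `genes.tsv`, `coords.tsv` and
#' `truth.tsv`.
#'
#' @param tissue output of [simulate_tissue()].
#' @param dir output directory.
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(tissue$counts, dir)
  write_coordinates(tissue$coords, file.path(dir, "coords.tsv"))
  write_labels(tissue$truth$id, tissue$truth$label,
               file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Spatial-vs-non-spatial recovery experiment
#'
#' Runs the full pipeline (normalize, feature selection, dimensionality
#' reduction, graph construction, clustering) on fresh simulations and
#' scores domain recovery. Non-spatial Leiden is run once per seed;
#' spatially aware clustering once per seed and spatial weight.
#'
#' @param spec a [tissue_spec]; its `seed` is replaced per repetition.
#' @param spatial_weights vector of spatial-layer weights; entries may be
#'   the string `"match"` for strength matching (see [spatialleiden()]).
#' @param n_seeds number of simulation repetitions.
#' @param feature_mode `"hvg"`, `"svg"` or `"all"`.
#' @param dimred_mode `"pca"` or `"multispati"`.
#' @param n_top,n_comp,latent_k pipeline sizes (defaults 3000, 30, 15).
#' @return data.frame(method, seed, weight, ari, nmi).
#' @export
recovery_experiment <- function(spec, spatial_weights = "match", n_seeds = 10,
                                feature_mode = "hvg", dimred_mode = "pca",
                                n_top = 3000, n_comp = 30, latent_k = 15) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    sp <- spec
    sp$seed <- spec$seed + s - 1L
    tis <- simulate_tissue(sp)
    pr <- prepare_tissue(tis, feature_mode = feature_mode,
                         dimred_mode = dimred_mode, n_top = n_top,
                         n_comp = n_comp, latent_k = latent_k,
                         seed = sp$seed)
    fit0 <- spatialleiden(pr$latent_graph, pr$spatial_graph,
                          spatial_weight = 0, target_k = spec$n_domains,
                          seed = derive_seed(sp$seed, "cluster"))
    m0 <- evaluate_partition(
      data.frame(id = tis$truth$id, label = fit0$membership), tis$truth)
    rows[[length(rows) + 1]] <-
      data.frame(method = "leiden", seed = sp$seed, weight = 0,
                 ari = m0$ari, nmi = m0$nmi)
    for (w in spatial_weights) {
      wn <- if (identical(w, "match")) "match" else as.numeric(w)
      fit <- spatialleiden(pr$latent_graph, pr$spatial_graph,
                           spatial_weight = wn, target_k = spec$n_domains,
                           seed = derive_seed(sp$seed, "cluster"))
      m <- evaluate_partition(
        data.frame(id = tis$truth$id, label = fit$membership), tis$truth)
      rows[[length(rows) + 1]] <-
        data.frame(method = "spatialleiden", seed = sp$seed,
                   weight = fit$spatial_weight, ari = m$ari, nmi = m$nmi)
    }
  }
  do.call(rbind, rows)
}

# shared preprocessing: normalize, select genes, reduce, build both graphs
prepare_tissue <- function(tissue, feature_mode = "hvg",
                           dimred_mode = "pca", n_top = 3000, n_comp = 30,
                           latent_k = 15, spatial_k = 10, seed = 0,
                           graph_mode = NULL) {
  logx <- normalize_log1p(tissue$counts)
  tech <- attr(tissue$coords, "technology")
  graph_mode <- graph_mode %||%
    if (tech %in% c("hex_grid", "square_grid")) "grid" else "knn"
  spatial_graph <- switch(graph_mode,
    grid = build_grid_graph(tissue$coords),
    delaunay = distances_to_connectivities(
      build_delaunay_graph(cbind(tissue$coords$x, tissue$coords$y))),
    knn = distances_to_connectivities(
      build_knn_graph(cbind(tissue$coords$x, tissue$coords$y), spatial_k)),
    stop_sm("unknown graph_mode '%s'", graph_mode))
  sel <- switch(feature_mode,
    hvg = subset_selected(logx, suppressWarnings(
      select_hvgs(tissue$counts, n_top = n_top))),
    svg = subset_selected(logx, suppressWarnings(
      select_svgs(logx, spatial_graph, n_top = n_top))),
    all = logx,
    stop_sm("unknown feature_mode '%s'", feature_mode))
  n_comp <- min(n_comp, dim(sel)[2], dim(sel)[1])
  model <- switch(dimred_mode,
    pca = multispati(sel, n_comp = n_comp),
    multispati = multispati(sel, spatial_graph, n_comp = n_comp),
    stop_sm("unknown dimred_mode '%s'", dimred_mode))
  latent_graph <- build_latent_knn(model$scores, k = latent_k)
  list(latent_graph = latent_graph, spatial_graph = spatial_graph,
       model = model, selected = sel)
}
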