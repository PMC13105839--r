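#' Configuration for the standard analysis pipeline
#'
#' Bundles the tunable parameters of [run_standard_pipeline()]: cell
#' filters on detected feature counts, the normalization variant, HVG
#' count, number of principal components for clustering, graph
#' neighbourhood size, and the seed consumed by every stochastic step.
#'
#' @param min_features,max_features keep cells detecting between these many
#'   genes (inclusive); `Inf` disables the upper filter. Defaults 200 and
#'   2500, the usual droplet-QC convention.
#' @param norm `"lognorm"` or `"clr"`.
#' @param scale_factor library-size target for `"lognorm"`.
#' @param n_hvg number of highly variable genes (default 2000).
#' @param n_pcs number of principal components (default 10).
#' @param graph_k neighbourhood size of the SNN clustering graph.
#' @param cluster_resolution Louvain resolution.
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed for PCA sign convention, clustering and t-SNE.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_features = 200, max_features = 2500,
                            norm = c("lognorm", "clr"), scale_factor = 1e4,
                            n_hvg = 2000, n_pcs = 10, graph_k = 20,
                            cluster_resolution = 1, perplexity = 30,
                            seed = 1L) {
  norm <- match.arg(norm)
  structure(list(min_features = min_features, max_features = max_features,
                 norm = norm, scale_factor = scale_factor, n_hvg = n_hvg,
                 n_pcs = n_pcs, graph_k = graph_k,
                 cluster_resolution = cluster_resolution,
                 perplexity = perplexity, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the standard scRNA-seq analysis pipeline
#'
#' The conventional workflow that produces the inputs of the trimming
#' functions: filter cells by detected feature counts, normalize
#' ([log_normalize()] or [clr_normalize()]), select highly variable genes,
#' z-scale per gene, PCA, Louvain community detection on a shared-nearest-
#' neighbour graph in PC space, and a seeded t-SNE embedding. Clustering
#' and embedding are delegated to established implementations; with a
#' fixed seed the run is repeatable.
#'
#' @param m an [expr_matrix()] with `layer = "counts"`.
#' @param cfg a [pipeline_config()].
#' @return A `pipeline_result` list: `normalized` (the normalized
#'   [expr_matrix()] of surviving cells), `hvg` (character vector),
#'   `clusters` (tibble `cell_id`, `cluster`), `embedding` (tibble
#'   `cell_id`, `x`, `y`), `pca` (cells x PCs matrix), `cfg`.
#' @export
run_standard_pipeline <- function(m, cfg = pipeline_config()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "pipeline_config"))
  if (m$layer != "counts")
    stop("the pipeline starts from a counts layer", call. = FALSE)
  detected <- Matrix::colSums(m$values > 0)
  keep <- detected >= cfg$min_features & detected <= cfg$max_features
  if (sum(keep) < 2)
    stop("fewer than 2 cells survive the feature-count filters",
         call. = FALSE)
  counts <- subset_expr(m, cells = cell_ids(m)[keep])
  normalized <- if (cfg$norm == "lognorm")
    log_normalize(counts, scale_factor = cfg$scale_factor)
  else clr_normalize(counts)
  hvg <- select_hvg(counts, n_features = cfg$n_hvg)

  x <- as.matrix(normalized$values[hvg, , drop = FALSE])
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  sd[sd == 0] <- 1
  z <- t((x - mu) / sd)                      # cells x genes
  z[z > 10] <- 10                            # standard scale clipping

  n_pcs <- min(cfg$n_pcs, ncol(z) - 1L, nrow(z) - 1L)
  pca <- with_seed(cfg$seed,
                   stats::prcomp(z, center = TRUE, scale. = FALSE,
                                 rank. = n_pcs))$x

  graph_k <- min(cfg$graph_k, nrow(pca) - 1L)
  nn <- FNN::get.knn(pca, k = graph_k)$nn.index
  labels <- with_seed(cfg$seed, snn_louvain(nn, cfg$cluster_resolution))
  emb <- embed_tsne(pca, seed = cfg$seed, perplexity = cfg$perplexity)

  structure(list(
    normalized = normalized,
    hvg = hvg,
    clusters = tibble::tibble(cell_id = cell_ids(normalized),
                              cluster = paste0("cluster-", labels)),
    embedding = tibble::tibble(cell_id = cell_ids(normalized),
                               x = emb[, 1], y = emb[, 2]),
    pca = pca,
    cfg = cfg), class = "pipeline_result")
}

# Louvain communities on a shared-nearest-neighbour graph built from a kNN
# index matrix (Jaccard edge weights, edges with overlap below 1/15 pruned
# as in the common SNN construction).
snn_louvain <- function(nn_index, resolution = 1) {
  n <- nrow(nn_index)
  k <- ncol(nn_index)
  neighb <- lapply(seq_len(n), function(i) c(i, nn_index[i, ]))
  edges <- list()
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn_index))
  pair <- cbind(pmin(from, to), pmax(from, to))
  pair <- unique(pair)
  jac <- vapply(seq_len(nrow(pair)), function(e) {
    a <- neighb[[pair[e, 1]]]
    b <- neighb[[pair[e, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- jac >= 1 / 15
  g <- igraph::graph_from_edgelist(pair[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = jac[keep])
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  igraph::membership(comm)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", ncol(x$normalized$values), " cells, ",
      length(x$hvg), " HVGs, ", length(unique(x$clusters$cluster)),
      " clusters (", x$cfg$norm, ", ", ncol(x$pca), " PCs, seed ",
      x$cfg$seed, ")\n", sep = "")
  invisible(x)
}

#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(n_cells = ncol(x$normalized$values),
                 n_genes = nrow(x$normalized$values),
                 n_hvg = length(x$hvg),
                 n_pcs = ncol(x$pca),
                 n_clusters = length(unique(x$clusters$cluster)),
                 norm = x$cfg$norm, seed = x$cfg$seed)
}
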