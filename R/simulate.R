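# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Locational-shift simulation scenario
#'
#' Describes a multivariate-normal cell cloud used to study where
#' high-dimensional extreme cells land in a 2-D embedding. Covariance
#' structures: `"dense"` (all pairwise correlations `rho`, the
#' high-covariance low-dimensional scenario), `"ar1"` (autoregressive,
#' correlation `rho^|i-j|`), `"block"` (`n_blocks` equal blocks with
#' within-block correlation `rho`), `"identity"`.
#'
#' @param n_cells number of cells (default 1000).
#' @param dim dimensionality (3 for the dense scenario, 100 for the
#'   autoregressive/block scenarios, by convention).
#' @param cov covariance structure.
#' @param rho correlation parameter; defaults 0.9 (dense), 0.5 (ar1), 0.6
#'   (block).
#' @param n_blocks number of blocks for `cov = "block"`.
#' @param seed mandatory RNG seed.
#' @return A `sim_scenario` list with the covariance matrix in `$sigma`.
#' @export
sim_scenario <- function(n_cells = 1000, dim = 3,
                         cov = c("dense", "ar1", "block", "identity"),
                         rho = NULL, n_blocks = 4, seed) {
  cov <- match.arg(cov)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rho <- rho %||% switch(cov, dense = 0.9, ar1 = 0.5, block = 0.6,
                         identity = 0)
  sigma <- switch(cov,
    dense = matrix(rho, dim, dim) + diag(1 - rho, dim),
    ar1 = rho^abs(outer(seq_len(dim), seq_len(dim), "-")),
    block = {
      sizes <- rep(dim %/% n_blocks, n_blocks)
      sizes[seq_len(dim %% n_blocks)] <- sizes[seq_len(dim %% n_blocks)] + 1L
      blocks <- lapply(sizes, function(s)
        matrix(rho, s, s) + diag(1 - rho, s))
      as.matrix(Matrix::bdiag(blocks))
    },
    identity = diag(dim))
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("covariance matrix is not positive-definite", call. = FALSE)
  structure(list(n_cells = n_cells, dim = dim, cov = cov, rho = rho,
                 sigma = sigma, seed = seed), class = "sim_scenario")
}

#' Draw a seeded multivariate-normal cell cloud
#'
#' Samples `n_cells` points from `N(0, sigma)` for a [sim_scenario()] and
#' attaches each cell's Mahalanobis distance to the generating distribution
#' as its ground-truth extremity (rank 1 = most extreme).
#'
#' @param s a [sim_scenario()].
#' @return A list: `coords` (n x dim matrix, rownames cell ids), `truth`
#'   (tibble `cell_id`, `mahalanobis`, `extremity_rank`), `scenario`.
#' @export
gen_gaussian_cloud <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  coords <- with_seed(s$seed,
                      MASS::mvrnorm(s$n_cells, mu = rep(0, s$dim),
                                    Sigma = s$sigma))
  rownames(coords) <- sprintf("cell-%d", seq_len(s$n_cells))
  maha <- stats::mahalanobis(coords, center = rep(0, s$dim), cov = s$sigma)
  list(coords = coords,
       truth = tibble::tibble(cell_id = rownames(coords),
                              mahalanobis = maha,
                              extremity_rank = rank(-maha,
                                                    ties.method = "first")),
       scenario = s)
}

#' Seeded t-SNE embedding
#'
#' Thin wrapper around a standard Barnes-Hut t-SNE for reproducible 2-D
#' embeddings of a coordinate or expression matrix.
#'
#' @param x numeric matrix, observations in rows.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   for small inputs).
#' @return An n x 2 matrix (columns `x`, `y`) with the rownames of `x`.
#' @export
embed_tsne <- function(x, seed, perplexity = 30) {
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  out <- with_seed(seed,
                   Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                                check_duplicates = FALSE, pca = FALSE,
                                verbose = FALSE))$Y
  dimnames(out) <- list(rownames(x), c("x", "y"))
  out
}

#' Border concordance of high-dimensional extremes in a 2-D embedding
#'
#' Measures whether the cells most extreme in the high-dimensional space
#' (top fraction `q` by Mahalanobis distance) land in the border area of a
#' 2-D embedding (top `2q` by distance to the embedding centroid). Returns
#' the fraction of the high-dimensional extremes found in the embedding
#' border set: 1 is perfect concordance, and under an embedding independent
#' of the extremity structure the expected score is `2q`.
#'
#' @param maha per-cell high-dimensional extremity (e.g. Mahalanobis
#'   distances from [gen_gaussian_cloud()]); a numeric vector aligned with
#'   the embedding rows, or named by cell id.
#' @param emb n x 2 matrix or `cell_id`/`x`/`y` tibble.
#' @param q fraction of cells treated as high-dimensional extremes, in
#'   `(0, 0.5]`.
#' @return Scalar score in `[0, 1]`.
#' @export
locational_shift_score <- function(maha, emb, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 0.5)
    stop("`q` must lie in (0, 0.5]", call. = FALSE)
  ids <- if (!is.null(names(maha))) names(maha) else
    if (is.data.frame(emb)) emb$cell_id else rownames(emb)
  if (is.null(ids)) ids <- sprintf("cell-%d", seq_along(maha))
  names(maha) <- ids
  xy <- align_embedding(emb, ids)
  n <- length(maha)
  n_hd <- max(1L, ceiling(q * n))
  n_2d <- max(1L, ceiling(2 * q * n))
  top_hd <- ids[order(-maha)[seq_len(n_hd)]]
  centroid <- colMeans(xy)
  d2c <- sqrt((xy[, 1] - centroid[1])^2 + (xy[, 2] - centroid[2])^2)
  top_2d <- ids[order(-d2c)[seq_len(n_2d)]]
  length(intersect(top_hd, top_2d)) / n_hd
}

#' Generate an scRNA-like count dataset with planted structure
#'
#' Negative-binomial counts for several clusters, with three planted
#' ground truths that make the trimming and robustness machinery testable:
#' (i) *border cells* — a fraction of each cluster drawn with
#' variance-inflated expression noise, pushing them to the sparsely
#' populated periphery of their cluster while keeping its identity;
#' (ii) *robust markers* — genes uniformly over-expressed across their
#' whole cluster; (iii) optionally one *fragile marker* per cluster,
#' expressed only in that cluster's border cells, whose marker status
#' should collapse once the border cells are trimmed.
#'
#' Each cell's expected expression is `mu_g * exp(z)` with
#' `z ~ N(0, noise_sd^2)` for core cells and variance `inflation *
#' noise_sd^2` for border cells; counts are NB with dispersion `nb_size`.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param cells_per_cluster cells per cluster.
#' @param n_genes background gene count (planted fragile genes are added on
#'   top).
#' @param markers_per_cluster robust marker genes per cluster.
#' @param base_mean median baseline NB mean; per-gene baselines are drawn
#'   log-normally around it (`sdlog = base_sdlog`), giving the spread of
#'   expression levels real data shows.
#' @param base_sdlog log-scale SD of the per-gene baseline means.
#' @param marker_fold fold elevation of robust markers in their cluster.
#' @param noise_sd cell-level log-normal noise SD for core cells.
#' @param outlier_frac fraction of border cells per cluster, in `[0, 0.5)`.
#' @param inflation variance inflation factor of border-cell noise
#'   (default 4, i.e. doubled SD).
#' @param nb_size NB size (inverse dispersion).
#' @param fragile if `TRUE`, add one border-only marker gene per cluster.
#' @param fragile_mean NB mean of the fragile gene in border cells.
#' @param seed mandatory RNG seed.
#' @return A `planted_dataset` list: `counts` ([expr_matrix()]), `labels`
#'   (tibble `cell_id`, `cluster`), `truth` (tibble with `is_border`),
#'   `marker_design` (tibble `cluster`, `gene`, `type`), `params`.
#' @export
gen_planted_dataset <- function(n_clusters = 3, cells_per_cluster = 100,
                                n_genes = 500, markers_per_cluster = 20,
                                base_mean = 2, base_sdlog = 1,
                                marker_fold = 8,
                                noise_sd = 0.5, outlier_frac = 0.1,
                                inflation = 4, nb_size = 10,
                                fragile = TRUE, fragile_mean = 50, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_clusters < 2) stop("need at least 2 clusters", call. = FALSE)
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop("`outlier_frac` must lie in [0, 0.5)", call. = FALSE)
  if (n_clusters * markers_per_cluster > n_genes)
    stop("not enough genes for the requested marker design", call. = FALSE)
  clusters <- paste0("cluster-", seq_len(n_clusters))
  genes <- sprintf("gene-%d", seq_len(n_genes))
  marker_design <- dplyr::bind_rows(purrr::map(seq_len(n_clusters),
    function(j) tibble::tibble(
      cluster = clusters[j],
      gene = genes[(j - 1) * markers_per_cluster + seq_len(markers_per_cluster)],
      type = "robust")))
  if (fragile) {
    frag <- tibble::tibble(cluster = clusters,
                           gene = paste0("fragile-", clusters),
                           type = "fragile")
    marker_design <- dplyr::bind_rows(marker_design, frag)
    genes <- c(genes, frag$gene)
  }
  n <- n_clusters * cells_per_cluster
  labels <- rep(clusters, each = cells_per_cluster)
  cell_ids <- sprintf("cell-%d", seq_len(n))
  n_border <- round(outlier_frac * cells_per_cluster)
  is_border <- rep(c(rep(TRUE, n_border),
                     rep(FALSE, cells_per_cluster - n_border)), n_clusters)

  counts <- with_seed(seed, {
    gene_base <- base_mean * exp(stats::rnorm(length(genes), 0, base_sdlog))
    mu_base <- matrix(gene_base, length(genes), n,
                      dimnames = list(genes, cell_ids))
    for (j in seq_len(n_clusters)) {
      in_cl <- labels == clusters[j]
      rob <- marker_design$gene[marker_design$cluster == clusters[j] &
                                  marker_design$type == "robust"]
      mu_base[rob, in_cl] <- gene_base[match(rob, genes)] * marker_fold
    }
    if (fragile) mu_base[grepl("^fragile-", genes), ] <- 0
    sd_cell <- ifelse(is_border, noise_sd * sqrt(inflation), noise_sd)
    z <- matrix(stats::rnorm(length(genes) * n), length(genes), n) *
      rep(sd_cell, each = length(genes))
    mu <- mu_base * exp(z)
    x <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
                length(genes), n, dimnames = dimnames(mu_base))
    if (fragile) for (j in seq_len(n_clusters)) {
      pick <- labels == clusters[j] & is_border
      g <- paste0("fragile-", clusters[j])
      x[g, pick] <- stats::rnbinom(sum(pick), mu = fragile_mean,
                                   size = nb_size)
    }
    x
  })

  structure(list(
    counts = expr_matrix(counts, layer = "counts"),
    labels = tibble::tibble(cell_id = cell_ids, cluster = labels),
    truth = tibble::tibble(cell_id = cell_ids, cluster = labels,
                           is_border = is_border),
    marker_design = marker_design,
    params = list(n_clusters = n_clusters,
                  cells_per_cluster = cells_per_cluster,
                  n_genes = n_genes,
                  markers_per_cluster = markers_per_cluster,
                  base_mean = base_mean, base_sdlog = base_sdlog,
                  marker_fold = marker_fold,
                  noise_sd = noise_sd, outlier_frac = outlier_frac,
                  inflation = inflation, nb_size = nb_size,
                  fragile = fragile, fragile_mean = fragile_mean,
                  seed = seed)),
    class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  p <- x$params
  cat("<planted_dataset> ", p$n_clusters, " clusters x ",
      p$cells_per_cluster, " cells, ", nrow(x$counts$values), " genes, ",
      round(100 * p$outlier_frac), "% border cells (seed ", p$seed, ")\n",
      sep = "")
  invisible(x)
}
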