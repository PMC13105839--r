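#' Per-cluster k-nearest-neighbour minimum distances
#'
#' For every cell, finds its `k` nearest neighbours *within its own cluster*
#' in the high-dimensional normalized expression space (Euclidean distance
#' over the selected feature rows) and records the sorted neighbour
#' distances `D_(1),...,D_(k)` and the extremity statistic
#' `min D = D_(1)`, the distance to the single closest same-cluster cell.
#' Cells with a large `min D` sit in sparsely populated, peripheral regions
#' of their cluster.
#'
#' Clusters with `c <= k` cells use an effective neighbourhood of `c - 1`
#' (all other members). Singleton clusters have no neighbour; their
#' `min_dist` is `+Inf` as a sentinel and a warning is raised — such cells
#' are never trimmed downstream.
#'
#' @param m an [expr_matrix()] with a normalized (`lognorm` or `clr`) layer.
#' @param clusters cluster labels (see [cluster_tbl()] for accepted forms).
#' @param k neighbourhood size; default 30, the usual convention for this
#'   statistic.
#' @param feature_set optional character vector of gene ids (e.g. the HVG
#'   set) on which distances are computed; default all genes.
#' @return A `knn_dist` tibble with one row per cell: `cell_id`, `cluster`,
#'   `k_eff`, `min_dist`, plus list-columns `neighbor_ids` and `nn_dist`
#'   (ascending). The neighbourhood size is stored in `attr(, "k")`.
#' @export
compute_min_knn_distance <- function(m, clusters, k = 30,
                                     feature_set = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer == "counts")
    stop("distances are computed on a normalized layer; run log_normalize()",
         " or clr_normalize() first", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  f <- align_clusters(clusters, m)
  if (!is.null(feature_set)) m <- subset_expr(m, genes = feature_set)
  x <- t(as.matrix(m$values))  # cells x features
  ids <- cell_ids(m)

  res <- lapply(split(seq_along(f), f), function(idx) {
    c_n <- length(idx)
    if (c_n == 1L) {
      warning("singleton cluster '", f[idx[1]],
              "': min_dist set to Inf, never trimmed", call. = FALSE)
      return(tibble::tibble(
        cell_id = ids[idx], k_eff = 0L, min_dist = Inf,
        neighbor_ids = list(character()), nn_dist = list(numeric())))
    }
    k_eff <- min(k, c_n - 1L)
    nn <- FNN::get.knn(x[idx, , drop = FALSE], k = k_eff)
    tibble::tibble(
      cell_id = ids[idx],
      k_eff = k_eff,
      min_dist = nn$nn.dist[, 1],
      neighbor_ids = lapply(seq_len(c_n), function(i)
        ids[idx[nn$nn.index[i, ]]]),
      nn_dist = lapply(seq_len(c_n), function(i) nn$nn.dist[i, ]))
  })
  out <- dplyr::bind_rows(res, .id = "cluster")
  out$cluster <- factor(out$cluster, levels = levels(f))
  out <- out[match(ids, out$cell_id),
             c("cell_id", "cluster", "k_eff", "min_dist",
               "neighbor_ids", "nn_dist")]
  attr(out, "k") <- k
  class(out) <- c("knn_dist", class(out))
  out
}

#' Flag extreme cells by quantile trimming of minimum kNN distances
#'
#' Per cluster, computes the empirical `(1 - alpha)` quantile (type-7,
#' linear interpolation) of the cells' minimum neighbour distances and flags
#' as `extreme` every cell whose `min_dist` lies strictly above it; all
#' other cells are `core`. `alpha` is the trimming fraction: `alpha = 0.1`
#' targets the 10% most peripheral cells of each cluster. Ties at the
#' threshold are kept as core (the rule is strict). Singleton clusters
#' (infinite sentinel `min_dist`) are always core, with a warning.
#'
#' @param nd a `knn_dist` tibble from [compute_min_knn_distance()].
#' @param alpha trimming fraction in `[0, 1)`.
#' @return A `trim_result` tibble: `cell_id`, `cluster`, `min_dist`,
#'   `threshold` (that cluster's quantile), `flag` (`"core"`/`"extreme"`);
#'   `attr(, "alpha")` records the trimming fraction.
#' @export
trim_cells <- function(nd, alpha) {
  stopifnot(is.data.frame(nd),
            all(c("cell_id", "cluster", "min_dist") %in% names(nd)))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("`alpha` must lie in [0, 1)", call. = FALSE)
  singleton <- !is.finite(nd$min_dist)
  if (any(singleton))
    warning(sum(singleton), " singleton cell(s) kept as core", call. = FALSE)
  cluster_threshold <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(Inf)
    stats::quantile(v, probs = 1 - alpha, type = 7, names = FALSE)
  }
  out <- tibble::tibble(cell_id = nd$cell_id,
                        cluster = factor(nd$cluster),
                        min_dist = nd$min_dist)
  thr <- vapply(split(out$min_dist, out$cluster), cluster_threshold,
                numeric(1))
  out$threshold <- unname(thr[as.character(out$cluster)])
  out$flag <- factor(ifelse(is.finite(out$min_dist) &
                              out$min_dist > out$threshold,
                            "extreme", "core"),
                     levels = c("core", "extreme"))
  attr(out, "alpha") <- alpha
  class(out) <- c("trim_result", class(out))
  out
}

#' Trim a dataset, keeping a fraction of cells per cluster
#'
#' Convenience composition of [compute_min_knn_distance()] and
#' [trim_cells()] with `alpha = 1 - keep_frac`: flags the extreme cells and
#' returns the expression matrix restricted to the core cells.
#'
#' @inheritParams compute_min_knn_distance
#' @param knn_k neighbourhood size (default 30).
#' @param keep_frac fraction of cells retained per cluster, in `(0, 1]`.
#' @return A list with elements `result` (the `trim_result` tibble) and
#'   `matrix` (the core-cell [expr_matrix()]).
#' @export
trim_dist <- function(m, clusters, knn_k = 30, keep_frac = 0.9,
                      feature_set = NULL) {
  if (!is.numeric(keep_frac) || length(keep_frac) != 1L ||
      keep_frac <= 0 || keep_frac > 1)
    stop("`keep_frac` must lie in (0, 1]", call. = FALSE)
  nd <- compute_min_knn_distance(m, clusters, k = knn_k,
                                 feature_set = feature_set)
  tr <- trim_cells(nd, alpha = 1 - keep_frac)
  keep <- tr$cell_id[tr$flag == "core"]
  list(result = tr, matrix = subset_expr(m, cells = keep))
}

#' @export
print.trim_result <- function(x, ...) {
  cat("<trim_result> alpha =", attr(x, "alpha"), "\n")
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @method tidy trim_result
#' @export
tidy.trim_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cell_id", "cluster", "min_dist",
                                 "threshold", "flag")])
}

#' Per-cluster summary of a trimming result
#'
#' @param x a `trim_result` from [trim_cells()].
#' @param ... unused.
#' @return One row per cluster: cell counts, extreme counts, threshold.
#' @method glance trim_result
#' @export
glance.trim_result <- function(x, ...) {
  tidy.trim_result(x) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_extreme = sum(.data$flag == "extreme"),
                     threshold = .data$threshold[1],
                     .groups = "drop") |>
    dplyr::mutate(alpha = attr(x, "alpha"))
}
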