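#' One-vs-rest marker detection per cluster
#'
#' For each cluster, tests every gene for differential expression between
#' the cluster's cells and all remaining cells with a two-sided Wilcoxon
#' rank-sum test, after a standard speed prefilter on detection rate and
#' fold change. The test uses the normal approximation with tie correction;
#' when both groups have at most `exact_max` cells the p-value is computed
#' by exhaustive enumeration over all group assignments instead.
#'
#' The log2 fold change is computed on de-logged means with a pseudocount:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. Detection
#' fractions `pct_in` / `pct_out` count cells with a value strictly above
#' zero. P-values are Bonferroni-adjusted over the genes actually tested in
#' that cluster: `p_adj = min(1, p * G_tested)`.
#'
#' @param m an [expr_matrix()] with a normalized layer.
#' @param clusters cluster labels (two or more clusters required).
#' @param min_pct keep genes detected in at least this fraction of cells in
#'   either group (default 0.1).
#' @param log2fc_min keep genes with `|log2fc|` at least this (default 0.25).
#' @param p_adj_max adjusted-p cutoff for reported rows (default 0.05).
#' @param only_positive keep only markers over-expressed in the cluster
#'   (default `TRUE`).
#' @param exact_max use exact enumeration when both group sizes are at most
#'   this (default 10).
#' @return A `marker_table` tibble: `cluster`, `gene`, `log2fc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj`, ordered by cluster then p.
#' @export
find_all_markers <- function(m, clusters, min_pct = 0.1, log2fc_min = 0.25,
                             p_adj_max = 0.05, only_positive = TRUE,
                             exact_max = 10L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer == "counts")
    stop("marker detection expects a normalized layer", call. = FALSE)
  f <- align_clusters(clusters, m)
  if (nlevels(f) < 2L)
    stop("need at least two clusters for one-vs-rest testing", call. = FALSE)
  x <- as.matrix(m$values)
  expd <- expm1(x)
  genes <- gene_ids(m)

  per_cluster <- lapply(levels(f), function(cl) {
    grp <- f == cl
    n1 <- sum(grp); n2 <- sum(!grp)
    pct_in <- rowMeans(x[, grp, drop = FALSE] > 0)
    pct_out <- rowMeans(x[, !grp, drop = FALSE] > 0)
    mean_in <- rowMeans(expd[, grp, drop = FALSE])
    mean_out <- rowMeans(expd[, !grp, drop = FALSE])
    log2fc <- log2((mean_in + 1) / (mean_out + 1))
    test <- pmax(pct_in, pct_out) >= min_pct & abs(log2fc) >= log2fc_min
    if (!any(test)) return(NULL)
    p <- wilcox_rank_sum(x[test, , drop = FALSE], grp,
                         exact_max = exact_max)
    tb <- tibble::tibble(
      cluster = cl, gene = genes[test],
      log2fc = unname(log2fc[test]), pct_in = unname(pct_in[test]),
      pct_out = unname(pct_out[test]),
      p = unname(p), p_adj = pmin(1, unname(p) * sum(test)))
    tb <- tb[tb$p_adj <= p_adj_max, , drop = FALSE]
    if (only_positive) tb <- tb[tb$log2fc > 0, , drop = FALSE]
    tb[order(tb$p, -abs(tb$log2fc)), , drop = FALSE]
  })
  out <- dplyr::bind_rows(per_cluster)
  if (nrow(out) == 0)
    out <- tibble::tibble(cluster = character(), gene = character(),
                          log2fc = double(), pct_in = double(),
                          pct_out = double(), p = double(), p_adj = double())
  out$cluster <- factor(out$cluster, levels = levels(f))
  class(out) <- c("marker_table", class(out))
  out
}

# Two-sided Wilcoxon rank-sum p-values for each row of `x` between cells
# with grp TRUE and grp FALSE. Normal approximation with tie correction and
# no continuity correction; exact enumeration over C(N, n1) assignments when
# both groups are small. Degenerate rows (all values tied) get p = 1.
wilcox_rank_sum <- function(x, grp, exact_max = 10L) {
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  stopifnot(n == ncol(x), n1 >= 1, n2 >= 1)
  ranks <- t(apply(x, 1L, rank))
  if (nrow(x) == 1L) ranks <- matrix(ranks, nrow = 1L)
  r1 <- rowSums(ranks[, grp, drop = FALSE])
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n, n1)
    mu <- n1 * (n + 1) / 2
    vapply(seq_len(nrow(x)), function(g) {
      sums <- colSums(matrix(ranks[g, idx], nrow = n1))
      dev <- abs(r1[g] - mu)
      mean(abs(sums - mu) >= dev - 1e-9)
    }, numeric(1))
  } else {
    mu <- n1 * (n + 1) / 2
    tie_term <- apply(ranks, 1L, function(r) {
      t <- table(r)
      sum(t^3 - t)
    })
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (r1 - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p[!is.finite(z)] <- 1
    pmin(p, 1)
  }
}

#' @method tidy marker_table
#' @export
tidy.marker_table <- function(x, ...) tibble::as_tibble(unclass(x))

#' Per-cluster marker counts
#'
#' @param x a `marker_table` from [find_all_markers()].
#' @param ... unused.
#' @return One row per cluster with the number of reported markers.
#' @method glance marker_table
#' @export
glance.marker_table <- function(x, ...) {
  tidy.marker_table(x) |>
    dplyr::count(.data$cluster, name = "n_markers", .drop = FALSE)
}
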