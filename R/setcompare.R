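#' Compare marker sets from full and trimmed analyses
#'
#' Given the per-cluster marker tables of a full analysis and a trimmed
#' reanalysis, forms for each cluster the sets `S1 = S_full \ S_trim`
#' (markers lost on trimming), `S2 = S_full` \eqn{\cap} `S_trim` (shared)
#' and `S3 = S_trim \ S_full` (gained), and their percentage proportions of
#' the union: `P_i = 100 |S_i| / m` with `m = |S_full` \eqn{\cup}
#' `S_trim|`. A large `P2` marks a robust cluster; large `P1` means the
#' full-data markers leaned on the trimmed border cells; large `P3` means
#' trimming changed the selection wholesale. Clusters where both sets are
#' empty (`m = 0`) get all proportions 0 and `empty = TRUE`.
#'
#' @param full,trimmed `marker_table` tibbles (from [find_all_markers()]),
#'   or any data frames with `cluster` and `gene` columns. Clusters present
#'   in only one table are compared against the empty set, with a warning.
#' @return A `set_comparison` tibble, one row per cluster: `n_full`,
#'   `n_trim`, `s1`, `s2`, `s3`, `m`, `p1`, `p2`, `p3`, `empty`, plus
#'   list-columns `genes_s1`, `genes_s2`, `genes_s3`.
#' @examples
#' full <- tibble::tibble(cluster = "A", gene = c("a", "b", "c"))
#' trim <- tibble::tibble(cluster = "A", gene = c("b", "c", "d"))
#' compare_marker_sets(full, trim)  # m = 4: P1 = 25, P2 = 50, P3 = 25
#' @export
compare_marker_sets <- function(full, trimmed) {
  stopifnot(all(c("cluster", "gene") %in% names(full)),
            all(c("cluster", "gene") %in% names(trimmed)))
  lev_f <- cluster_universe(full)
  lev_t <- cluster_universe(trimmed)
  only_one <- c(setdiff(lev_f, lev_t), setdiff(lev_t, lev_f))
  if (length(only_one))
    warning("clusters present in only one table, compared against the ",
            "empty set: ", paste(only_one, collapse = ", "), call. = FALSE)
  lev <- union(lev_f, lev_t)
  sets_f <- split(as.character(full$gene), factor(full$cluster, lev))
  sets_t <- split(as.character(trimmed$gene), factor(trimmed$cluster, lev))
  g1 <- g2 <- g3 <- vector("list", length(lev))
  n_full <- n_trim <- integer(length(lev))
  for (i in seq_along(lev)) {
    sf <- unique(sets_f[[i]]); st <- unique(sets_t[[i]])
    g1[[i]] <- setdiff(sf, st)
    g2[[i]] <- intersect(sf, st)
    g3[[i]] <- setdiff(st, sf)
    n_full[i] <- length(sf); n_trim[i] <- length(st)
  }
  s1 <- lengths(g1); s2 <- lengths(g2); s3 <- lengths(g3)
  m <- s1 + s2 + s3
  denom <- ifelse(m == 0, 1L, m)   # m = 0 gives all proportions 0
  tibble::new_tibble(list(
    cluster = factor(lev, levels = lev),
    n_full = n_full, n_trim = n_trim,
    s1 = s1, s2 = s2, s3 = s3, m = m,
    p1 = 100 * s1 / denom, p2 = 100 * s2 / denom, p3 = 100 * s3 / denom,
    empty = m == 0,
    genes_s1 = g1, genes_s2 = g2, genes_s3 = g3),
    nrow = length(lev), class = "set_comparison")
}

cluster_universe <- function(tb) {
  if (is.factor(tb$cluster)) levels(tb$cluster) else
    unique(as.character(tb$cluster))
}

#' Long-format heatmap table of a set comparison
#'
#' @param x a `set_comparison`.
#' @param ... unused.
#' @return Tibble with one row per cluster x category (`S1`, `S2`, `S3`):
#'   `count`, `pct` (0-100), and the full/trimmed totals used as the
#'   parenthesized row annotations of the comparison heatmap.
#' @method tidy set_comparison
#' @export
tidy.set_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |>
    dplyr::select("cluster", "n_full", "n_trim", "s1", "s2", "s3",
                  "p1", "p2", "p3") |>
    tidyr::pivot_longer(cols = c("s1", "s2", "s3", "p1", "p2", "p3"),
                        names_to = c(".value", "category"),
                        names_pattern = "(s|p)([123])") |>
    dplyr::mutate(category = factor(paste0("S", .data$category),
                                    levels = c("S1", "S2", "S3"))) |>
    dplyr::rename(count = "s", pct = "p")
}

#' @method glance set_comparison
#' @export
glance.set_comparison <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x),
                 mean_p2 = mean(x$p2[!x$empty]),
                 min_p2 = ifelse(any(!x$empty), min(x$p2[!x$empty]), NA_real_),
                 n_empty = sum(x$empty))
}

# Normalize + HVG selection for one analysis variant.
variant_prepare <- function(counts, variant) {
  norm <- match.arg(variant$norm %||% "lognorm", c("lognorm", "clr"))
  n_hvg <- variant$n_hvg %||% 2000
  nm <- if (norm == "lognorm")
    log_normalize(counts, scale_factor = variant$scale_factor %||% 1e4)
  else clr_normalize(counts)
  list(norm = nm, hvg = select_hvg(counts, n_features = n_hvg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-vs-trimmed marker comparison under two analysis variants
#'
#' Runs the complete robustness contrast: under each of two analysis
#' variants (e.g. two normalizations, or two HVG counts), markers are
#' detected on the full data and again after trimming the most extreme
#' cells per cluster, and the two marker tables are compared with
#' [compare_marker_sets()]. Cluster labels are fixed before trimming;
#' trimming never re-clusters.
#'
#' @param counts an [expr_matrix()] with `layer = "counts"`.
#' @param clusters cluster labels.
#' @param variant_a,variant_b lists describing each variant: `norm`
#'   (`"lognorm"` or `"clr"`), `n_hvg`, optional `scale_factor`.
#' @param knn_k neighbourhood size for trimming (default 30).
#' @param keep_frac fraction of cells kept per cluster (default 0.9, i.e.
#'   10% trimming).
#' @param ... passed to [find_all_markers()] (e.g. `min_pct`).
#' @return A `trim_effect` object: list with `comparisons` (named list of
#'   two `set_comparison` tibbles) and `heatmap` (their combined long
#'   table, with a `variant` column). `tidy()` returns the heatmap table.
#' @export
trim_effect <- function(counts, clusters,
                        variant_a = list(norm = "lognorm", n_hvg = 2000),
                        variant_b = list(norm = "clr", n_hvg = 2000),
                        knn_k = 30, keep_frac = 0.9, ...) {
  stopifnot(inherits(counts, "expr_matrix"))
  variants <- list(a = variant_a, b = variant_b)
  names(variants) <- c(variant_label(variant_a, "a"),
                       variant_label(variant_b, "b"))
  comparisons <- purrr::map(variants, function(v) {
    prep <- variant_prepare(counts, v)
    full <- find_all_markers(prep$norm, clusters, ...)
    tr <- trim_dist(prep$norm, clusters, knn_k = knn_k,
                    keep_frac = keep_frac, feature_set = prep$hvg)
    keep <- tr$result$cell_id[tr$result$flag == "core"]
    trimmed <- find_all_markers(subset_expr(prep$norm, cells = keep),
                                clusters = cluster_subset(clusters, keep,
                                                          prep$norm), ...)
    compare_marker_sets(full, trimmed)
  })
  heatmap <- purrr::imap(comparisons,
                         ~ dplyr::mutate(tidy(.x), variant = .y)) |>
    dplyr::bind_rows() |>
    dplyr::mutate(variant = factor(.data$variant, levels = names(variants)))
  structure(list(comparisons = comparisons, heatmap = heatmap),
            class = "trim_effect")
}

variant_label <- function(v, fallback) {
  v$label %||% paste0(v$norm %||% "lognorm", "/hvg", v$n_hvg %||% 2000)
}

# Restrict a cluster assignment to a kept-cell subset, preserving form.
cluster_subset <- function(clusters, keep, m) {
  f <- align_clusters(clusters, m)
  tibble::tibble(cell_id = keep,
                 cluster = as.character(f[keep]))
}

#' @export
print.trim_effect <- function(x, ...) {
  cat("<trim_effect> variants:", paste(names(x$comparisons),
                                       collapse = " vs "), "\n")
  for (nm in names(x$comparisons)) {
    cat("--", nm, "--\n")
    print(tibble::as_tibble(unclass(x$comparisons[[nm]]))[
      , c("cluster", "n_full", "n_trim", "p1", "p2", "p3")])
  }
  invisible(x)
}

#' @method tidy trim_effect
#' @export
tidy.trim_effect <- function(x, ...) x$heatmap

#' Marker retention across increasing trimming levels
#'
#' Breakdown-point profile of marker selection: markers are recomputed at
#' each trimming level and compared against the fixed untrimmed baseline
#' `S_full`; retention is `100 |S_full` \eqn{\cap} `S_trim(alpha)| /
#' |S_full|`. The neighbour distances are computed once; only the quantile
#' threshold moves with the level. Clusters with an empty baseline get
#' `NA` retention.
#'
#' @param counts an [expr_matrix()] with `layer = "counts"`.
#' @param clusters cluster labels.
#' @param levels trimming fractions, ascending, starting at 0; default
#'   `c(0, 0.1, 0.2, 0.3, 0.4)`.
#' @param norm normalization variant, `"lognorm"` or `"clr"`.
#' @param n_hvg HVG count for the trimming feature space.
#' @param knn_k neighbourhood size (default 30).
#' @param ... passed to [find_all_markers()].
#' @return A `breakdown_profile` tibble: `cluster`, `n_full`, `level`
#'   (trimming fraction), `trim_pct`, `retention` (0-100).
#' @export
breakdown_profile <- function(counts, clusters,
                              levels = c(0, 0.1, 0.2, 0.3, 0.4),
                              norm = "lognorm", n_hvg = 2000, knn_k = 30,
                              ...) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (is.unsorted(levels, strictly = TRUE) || levels[1] != 0 ||
      any(levels < 0 | levels >= 1))
    stop("`levels` must be strictly ascending trimming fractions in ",
         "[0, 1) starting at 0", call. = FALSE)
  prep <- variant_prepare(counts, list(norm = norm, n_hvg = n_hvg))
  full <- find_all_markers(prep$norm, clusters, ...)
  s_full <- purrr::map(split(as.character(full$gene), full$cluster), unique)
  nd <- compute_min_knn_distance(prep$norm, clusters, k = knn_k,
                                 feature_set = prep$hvg)
  rows <- purrr::map(levels, function(alpha) {
    if (alpha == 0) {
      st <- s_full
    } else {
      tr <- trim_cells(nd, alpha = alpha)
      keep <- tr$cell_id[tr$flag == "core"]
      trimmed <- find_all_markers(
        subset_expr(prep$norm, cells = keep),
        clusters = cluster_subset(clusters, keep, prep$norm), ...)
      st <- split(as.character(trimmed$gene), trimmed$cluster)
    }
    purrr::imap(s_full, function(sf, cl) {
      tibble::tibble(
        cluster = cl, n_full = length(sf), level = alpha,
        trim_pct = 100 * alpha,
        retention = if (length(sf) == 0) NA_real_ else
          100 * length(intersect(sf, unique(st[[cl]]))) / length(sf))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$cluster <- factor(rows$cluster, levels = names(s_full))
  class(rows) <- c("breakdown_profile", class(rows))
  rows
}

#' @method tidy breakdown_profile
#' @export
tidy.breakdown_profile <- function(x, ...) tibble::as_tibble(unclass(x))
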