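#' Alpha-hull boundaries of clusters in a 2-D embedding
#'
#' Computes one alpha-hull boundary per cluster from the cells' embedding
#' coordinates. An edge between two member points is part of the boundary
#' when an open disc of radius `hull_alpha` through both endpoints contains
#' no other member point (the alpha-extreme-edge criterion); candidate
#' edges are restricted to the Delaunay triangulation, of which every
#' boundary edge is a subset. The circular arcs of the exact alpha hull are
#' represented by the straight chords between boundary points, which is the
#' resolution at which distance queries are made. As `hull_alpha` grows the
#' boundary converges to the convex hull; small values give tighter,
#' concave outlines.
#'
#' Degenerate clusters (fewer than 3 points, or collinear) fall back to
#' their convex hull (a segment or a point) with a warning.
#'
#' @param emb embedding: a tibble with columns `cell_id`, `x`, `y` (see
#'   [read_embedding_tsv()]) or an n x 2 matrix with cell ids as rownames.
#' @param clusters cluster labels for the same cells.
#' @param hull_alpha positive concavity radius, in embedding units.
#' @return An `alpha_hulls` object: a named list (one entry per cluster) of
#'   lists with `points` (member coordinates), `edges` (two-column index
#'   matrix of boundary segments), `loops` (boundary vertex sequences, for
#'   plotting), and `members` (cell ids).
#' @export
compute_alpha_hull <- function(emb, clusters, hull_alpha) {
  if (!is.numeric(hull_alpha) || length(hull_alpha) != 1L || hull_alpha <= 0)
    stop("`hull_alpha` must be a positive number", call. = FALSE)
  prep <- hull_inputs(emb, clusters)
  hulls <- lapply(split(seq_len(nrow(prep$xy)), prep$f), function(idx) {
    pts <- prep$xy[idx, , drop = FALSE]
    edges <- alpha_boundary_edges(pts, hull_alpha)
    list(points = pts, edges = edges, loops = chain_loops(edges),
         members = rownames(pts))
  })
  structure(hulls, hull_alpha = hull_alpha, class = "alpha_hulls")
}

hull_inputs <- function(emb, clusters) {
  if (is.data.frame(clusters)) {
    ids <- as.character(clusters$cell_id)
    f <- droplevels(factor(stats::setNames(as.character(clusters$cluster),
                                           ids)[ids]))
  } else if (!is.null(names(clusters))) {
    ids <- names(clusters)
    f <- droplevels(factor(as.character(clusters)))
    names(f) <- ids
  } else stop("clusters must be a cell_id/cluster data frame or a named ",
              "vector", call. = FALSE)
  xy <- align_embedding(emb, ids)
  list(xy = xy, f = f)
}

# Boundary edges of the alpha shape of a 2-D point set. For each candidate
# edge (Delaunay when available and n >= 4, otherwise all pairs) the two
# discs of radius `alpha` through its endpoints are tested for emptiness.
# Collinear/small sets fall back to consecutive convex-hull segments.
alpha_boundary_edges <- function(pts, alpha, tol = 1e-9) {
  n <- nrow(pts)
  if (any(!is.finite(pts))) stop("non-finite coordinates", call. = FALSE)
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  degenerate <- n < 3L || span == 0 || collinear(pts)
  if (degenerate) {
    warning("degenerate cluster (", n, " points): convex-hull fallback",
            call. = FALSE)
    if (n == 1L || span == 0) return(matrix(integer(), 0, 2))
    h <- grDevices::chull(pts)
    if (length(h) < 2L) h <- seq_len(n)
    return(cbind(h, c(h[-1], h[1]))[seq_len(max(1, length(h) - (n == 2L))),
                                    , drop = FALSE])
  }
  cand <- delaunay_edges(pts)
  d2 <- (pts[cand[, 1], 1] - pts[cand[, 2], 1])^2 +
    (pts[cand[, 1], 2] - pts[cand[, 2], 2])^2
  cand <- cand[d2 <= (2 * alpha)^2 * (1 + tol), , drop = FALSE]
  keep <- vapply(seq_len(nrow(cand)), function(e) {
    i <- cand[e, 1]; j <- cand[e, 2]
    p <- pts[i, ]; q <- pts[j, ]
    mid <- (p + q) / 2
    d <- sqrt(sum((p - q)^2))
    h2 <- alpha^2 - (d / 2)^2
    h <- sqrt(max(h2, 0))
    perp <- if (d > 0) c(q[2] - p[2], p[1] - q[1]) / d else c(1, 0)
    others <- pts[-c(i, j), , drop = FALSE]
    eps <- alpha * 1e-9
    for (s in c(1, -1)) {
      ctr <- mid + s * h * perp
      if (nrow(others) == 0) return(TRUE)
      dd <- sqrt((others[, 1] - ctr[1])^2 + (others[, 2] - ctr[2])^2)
      if (all(dd >= alpha - eps)) return(TRUE)
    }
    FALSE
  }, logical(1))
  cand[keep, , drop = FALSE]
}

collinear <- function(pts, tol = 1e-10) {
  if (nrow(pts) < 3L) return(TRUE)
  p <- sweep(pts, 2, pts[1, ])
  a <- p[which.max(rowSums(p^2)), ]  # reference direction
  if (all(a == 0)) return(TRUE)
  scale <- max(1, max(abs(p)))
  all(abs(p[, 1] * a[2] - p[, 2] * a[1]) <= tol * scale^2)
}

delaunay_edges <- function(pts) {
  n <- nrow(pts)
  if (n >= 4L && requireNamespace("deldir", quietly = TRUE)) {
    dxy <- suppressWarnings(
      deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE))
    e <- as.matrix(dxy$delsgs[, c("ind1", "ind2")])
    dimnames(e) <- NULL
    e
  } else {
    t(utils::combn(n, 2))
  }
}

# Order boundary edges into closed (or, for degenerate hulls, open) vertex
# sequences by following shared endpoints.
chain_loops <- function(edges) {
  if (nrow(edges) == 0) return(list())
  remaining <- edges
  loops <- list()
  while (nrow(remaining) > 0) {
    path <- as.integer(remaining[1, ])
    remaining <- remaining[-1, , drop = FALSE]
    repeat {
      tail_v <- path[length(path)]
      hit <- which(remaining[, 1] == tail_v | remaining[, 2] == tail_v)
      if (!length(hit)) break
      e <- remaining[hit[1], ]
      remaining <- remaining[-hit[1], , drop = FALSE]
      path <- c(path, if (e[1] == tail_v) e[2] else e[1])
      if (path[length(path)] == path[1]) break
    }
    loops[[length(loops) + 1L]] <- path
  }
  loops
}

#' Total enclosed area of an alpha hull
#'
#' Shoelace area summed over the hull's closed boundary loops; open
#' (degenerate) boundaries contribute zero. Holes are not subtracted.
#'
#' @param hull one element of an `alpha_hulls` object.
#' @return Non-negative area.
#' @export
hull_area <- function(hull) {
  sum(vapply(hull$loops, function(loop) {
    if (length(loop) < 4L || loop[1] != loop[length(loop)]) return(0)
    v <- hull$points[loop[-length(loop)], , drop = FALSE]
    abs(sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
              v[c(2:nrow(v), 1), 1] * v[, 2])) / 2
  }, numeric(1)))
}

#' Minimum distance from each cell to its cluster's hull boundary
#'
#' Euclidean distance from the cell's embedding coordinate to the nearest
#' point of its own cluster's boundary segments. Cells whose coordinate
#' lies on the boundary (hull vertices in particular) get 0.
#'
#' @param emb embedding (as in [compute_alpha_hull()]).
#' @param hulls an `alpha_hulls` object covering every cluster.
#' @param clusters cluster labels for the same cells.
#' @return Tibble: `cell_id`, `cluster`, `dist_to_hull`.
#' @export
distance_to_hull <- function(emb, hulls, clusters) {
  prep <- hull_inputs(emb, clusters)
  rows <- purrr::map(levels(prep$f), function(cl) {
    hull <- hulls[[cl]]
    if (is.null(hull)) stop("no hull for cluster ", cl, call. = FALSE)
    idx <- which(prep$f == cl)
    pts <- prep$xy[idx, , drop = FALSE]
    d <- point_segments_dist(pts, hull)
    tibble::tibble(cell_id = rownames(prep$xy)[idx], cluster = cl,
                   dist_to_hull = d)
  })
  out <- dplyr::bind_rows(rows)
  out$cluster <- factor(out$cluster, levels = levels(prep$f))
  out[match(rownames(prep$xy), out$cell_id), ]
}

point_segments_dist <- function(pts, hull) {
  edges <- hull$edges
  hp <- hull$points
  if (nrow(edges) == 0) {
    # point-hull: distance to the (single) member point
    return(sqrt((pts[, 1] - hp[1, 1])^2 + (pts[, 2] - hp[1, 2])^2))
  }
  d <- rep(Inf, nrow(pts))
  for (e in seq_len(nrow(edges))) {
    a <- hp[edges[e, 1], ]; b <- hp[edges[e, 2], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                         (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Flag near-border cells by their distance to the cluster hull
#'
#' The embedding-level trimming variant: builds per-cluster alpha hulls,
#' computes each cell's minimum distance to its own cluster's boundary, and
#' flags as `extreme` the cells whose distance lies strictly *below* the
#' cluster's empirical `outlier_quantile` quantile (type-7) of those
#' distances — i.e. the cells hugging the border. Larger quantiles flag
#' more peripheral cells; 0 flags none.
#'
#' Note that this variant inspects the 2-D embedding only; the
#' high-dimensional [trim_cells()] route is the recommended default, since
#' embeddings can shift individual extreme cells away from the border.
#'
#' @inheritParams compute_alpha_hull
#' @param outlier_quantile quantile cutoff in `[0, 1]`.
#' @return A `hull_trim_result` tibble: `cell_id`, `cluster`,
#'   `dist_to_hull`, `threshold`, `flag`; the hulls are attached as
#'   `attr(, "hulls")` and the quantile as `attr(, "outlier_quantile")`.
#' @export
trim_hull <- function(emb, clusters, hull_alpha, outlier_quantile) {
  if (!is.numeric(outlier_quantile) || length(outlier_quantile) != 1L ||
      outlier_quantile < 0 || outlier_quantile > 1)
    stop("`outlier_quantile` must lie in [0, 1]", call. = FALSE)
  hulls <- compute_alpha_hull(emb, clusters, hull_alpha)
  d <- distance_to_hull(emb, hulls, clusters)
  out <- d |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(threshold = stats::quantile(.data$dist_to_hull,
                                              probs = outlier_quantile,
                                              type = 7, names = FALSE),
                  flag = ifelse(.data$dist_to_hull < .data$threshold,
                                "extreme", "core")) |>
    dplyr::ungroup()
  out$flag <- factor(out$flag, levels = c("core", "extreme"))
  attr(out, "hulls") <- hulls
  attr(out, "outlier_quantile") <- outlier_quantile
  class(out) <- c("hull_trim_result", class(out))
  out
}

#' @method tidy hull_trim_result
#' @export
tidy.hull_trim_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cell_id", "cluster", "dist_to_hull",
                                 "threshold", "flag")])
}
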