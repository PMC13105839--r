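#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Embedding overlay of trimmed cells
#'
#' Scatter plot of the 2-D embedding, cells coloured by cluster, with the
#' cells flagged `extreme` outlined in black — the standard way to inspect
#' which cells a trimming run would remove.
#'
#' @param object a `trim_result` (from [trim_cells()]) or
#'   `hull_trim_result` (from [trim_hull()]).
#' @param emb embedding tibble (`cell_id`, `x`, `y`) or n x 2 matrix;
#'   required for `trim_result` (hull results carry their own coordinates
#'   only through `emb` too).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trim_result
#' @export
autoplot.trim_result <- function(object, emb, ...) {
  df <- tidy(object)
  xy <- align_embedding(emb, df$cell_id)
  df$x <- xy[, 1]; df$y <- xy[, 2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[df$flag == "extreme", , drop = FALSE],
                        colour = "black", size = 2.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 1.4) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trim_result
#' @method autoplot hull_trim_result
#' @export
autoplot.hull_trim_result <- function(object, emb, ...) {
  p <- autoplot.trim_result(object, emb, ...)
  hulls <- attr(object, "hulls")
  segs <- dplyr::bind_rows(purrr::imap(hulls, function(h, cl) {
    if (nrow(h$edges) == 0) return(NULL)
    tibble::tibble(cluster = cl,
                   x = h$points[h$edges[, 1], 1],
                   y = h$points[h$edges[, 1], 2],
                   xend = h$points[h$edges[, 2], 1],
                   yend = h$points[h$edges[, 2], 2])
  }))
  if (nrow(segs))
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      linewidth = 0.3, colour = "grey30")
  p
}

#' Marker-set comparison heatmap
#'
#' Tile heatmap of the S1/S2/S3 percentages per cluster (white 0% to red
#' 100%), the standard display of a full-vs-trimmed marker comparison;
#' `trim_effect` objects get one column block per analysis variant.
#'
#' @param object a `set_comparison` or `trim_effect`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot set_comparison
#' @export
autoplot.set_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$cluster,
                                   fill = .data$pct)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$pct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 100), name = "% of union") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.set_comparison
#' @method autoplot trim_effect
#' @export
autoplot.trim_effect <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$cluster,
                                   fill = .data$pct)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 100), name = "% of union") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Breakdown-point retention heatmap
#'
#' Clusters (rows, labelled with their baseline marker counts) against
#' trimming percentage, filled by the percentage of the original marker
#' set retained (red 0% to blue 100%).
#'
#' @param object a `breakdown_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot breakdown_profile
#' @export
autoplot.breakdown_profile <- function(object, ...) {
  df <- tidy(object)
  df$row <- sprintf("%s (%d)", df$cluster, df$n_full)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$trim_pct),
                                   y = .data$row,
                                   fill = .data$retention)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$retention), "-",
                     sprintf("%.0f", .data$retention))), size = 3) +
    ggplot2::scale_fill_gradient(low = "red", high = "blue",
                                 limits = c(0, 100), na.value = "grey90",
                                 name = "% retained") +
    ggplot2::labs(x = "trimming level (%)", y = NULL) +
    ggplot2::theme_minimal()
}
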