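#' Library-size log-normalization
#'
#' Scales each cell to a common library size and log-transforms: a count `x`
#' in cell `c` becomes `ln(1 + scale_factor * x / total(c))`, where
#' `total(c)` is the cell's count sum. This is the standard per-cell
#' "LogNormalize" transform.
#'
#' @param m an [expr_matrix()] with `layer = "counts"`.
#' @param scale_factor positive library-size target; default 10000.
#' @return An [expr_matrix()] with `layer = "lognorm"`.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "counts")
    stop("log_normalize expects a counts layer, got ", m$layer, call. = FALSE)
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      scale_factor <= 0)
    stop("`scale_factor` must be a positive number", call. = FALSE)
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(utils::head(cell_ids(m)[totals == 0], 5), collapse = ", "),
         call. = FALSE)
  v <- m$values %*% Matrix::Diagonal(x = scale_factor / totals)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$values)
  expr_matrix(v, layer = "lognorm")
}

#' Centered log-ratio normalization
#'
#' Within each cell, a count `x` becomes `ln(1 + x / g(c))` where `g(c)` is
#' the geometric-mean term `exp(mean_g ln(1 + x_g))`, the mean running over
#' all genes of that cell (zeros included). A cell with all-zero counts maps
#' to all zeros, since its geometric-mean term is `exp(0) = 1`.
#'
#' @param m an [expr_matrix()] with `layer = "counts"`.
#' @return An [expr_matrix()] with `layer = "clr"`.
#' @export
clr_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "counts")
    stop("clr_normalize expects a counts layer, got ", m$layer, call. = FALSE)
  lp <- m$values
  lp@x <- log1p(lp@x)
  geo <- exp(Matrix::colSums(lp) / nrow(lp))
  v <- m$values %*% Matrix::Diagonal(x = 1 / geo)
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$values)
  expr_matrix(v, layer = "clr")
}

#' Highly variable gene selection by standardized variance
#'
#' Ranks genes by their variance after standardization against a
#' mean-variance trend, the usual variance-stabilizing ("vst") selection:
#' a loess curve of `log10(variance)` on `log10(mean)` predicts each gene's
#' expected standard deviation; counts are standardized against it, clipped
#' at `sqrt(n)`, and the variance of the clipped values ranks the genes.
#' Selection operates on raw counts and is fully deterministic.
#'
#' @param m an [expr_matrix()] with `layer = "counts"`.
#' @param n_features number of genes to select; capped at the number of
#'   genes present.
#' @param loess_span span of the mean-variance trend fit.
#' @return Character vector of `min(n_features, d)` gene ids, ranked by
#'   decreasing standardized variance.
#' @export
select_hvg <- function(m, n_features = 2000, loess_span = 0.3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "counts")
    stop("select_hvg expects a counts layer, got ", m$layer, call. = FALSE)
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 1)
    stop("`n_features` must be a positive integer", call. = FALSE)
  v <- standardized_variance(m$values, loess_span)
  ord <- order(-v)
  gene_ids(m)[ord[seq_len(min(floor(n_features), nrow(m$values)))]]
}

# Variance of trend-standardized counts, clipped at sqrt(n) (per-gene score
# used by select_hvg). Falls back from loess to a linear trend when the fit
# degenerates (few genes / few distinct means).
standardized_variance <- function(counts, loess_span = 0.3) {
  n <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  sigma2 <- (ex2 - mu^2) * n / (n - 1)
  out <- numeric(nrow(counts))
  ok <- sigma2 > 0 & mu > 0
  if (!any(ok)) return(out)
  if (sum(ok) < 5 || length(unique(mu[ok])) < 3) {
    # too few variable genes to fit a trend: plain dispersion ranking
    out[ok] <- sigma2[ok] / mu[ok]
    return(out)
  }
  lx <- log10(mu[ok]); ly <- log10(sigma2[ok])
  fit_sd <- tryCatch({
    fit <- stats::loess(ly ~ lx, span = loess_span, degree = 2)
    sqrt(10^stats::predict(fit, lx))
  }, error = function(e) {
    co <- stats::coef(stats::lm(ly ~ lx))
    sqrt(10^(co[1] + co[2] * lx))
  })
  fit_sd[!is.finite(fit_sd)] <- sqrt(sigma2[ok])[!is.finite(fit_sd)]
  clip <- sqrt(n)
  dense <- as.matrix(counts[ok, , drop = FALSE])
  z <- (dense - mu[ok]) / fit_sd
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  mz <- rowMeans(z)
  out[ok] <- rowSums((z - mz)^2) / (n - 1)
  out
}
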