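# Shared fixtures and independent oracles for the test suite.

make_counts <- function(x, nrow, ncol) {
  expr_matrix(matrix(x, nrow, ncol,
                     dimnames = list(sprintf("g%d", seq_len(nrow)),
                                     sprintf("c%d", seq_len(ncol)))))
}

# Wrap an arbitrary numeric matrix as a normalized-layer container.
as_lognorm <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%d", seq_len(ncol(x)))
  expr_matrix(x, layer = "lognorm")
}

# Brute-force oracle: per-cell minimum within-cluster distance from the
# full pairwise distance matrix (cells in columns of `em`).
brute_min_dist <- function(em, labels) {
  x <- t(as.matrix(em$values))
  out <- rep(NA_real_, nrow(x))
  names(out) <- rownames(x)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 1) { out[idx] <- Inf; next }
    dm <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
    diag(dm) <- Inf
    out[idx] <- apply(dm, 1, min)
  }
  out
}

# Independent textbook rank-sum oracle: U statistic counted pairwise,
# tie-corrected normal approximation, no continuity correction.
oracle_wilcox_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * n2 / 2
  r <- rank(c(a, b))
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  2 * stats::pnorm(-abs((u - mu) / sqrt(sigma2)))
}

# One-cluster label helper.
one_cluster <- function(em, label = "A") {
  stats::setNames(rep(label, ncol(em$values)), cell_ids(em))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
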