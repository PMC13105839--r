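test_that("minimum kNN distances match hand-computed cases", {
  # two coincident cells
  em <- as_lognorm(matrix(c(1, 1), 1, 2))
  nd <- compute_min_knn_distance(em, one_cluster(em), k = 1)
  expect_equal(nd$min_dist, c(0, 0))

  # 1-feature cluster at positions 0,1,3,7 with k = 2
  em2 <- as_lognorm(matrix(c(0, 1, 3, 7), 1, 4))
  nd2 <- compute_min_knn_distance(em2, one_cluster(em2), k = 2)
  expect_equal(nd2$min_dist, c(1, 1, 2, 4))
  expect_equal(nd2$nn_dist[[1]], c(1, 3))   # sorted ascending
  expect_equal(nd2$k_eff, rep(2L, 4))

  # default neighbourhood size is 30
  expect_identical(formals(compute_min_knn_distance)$k, 30)

  # neighbours come from the same cluster only, never self
  set.seed(10)
  em3 <- as_lognorm(matrix(abs(rnorm(80)), 4, 20))
  lab <- setNames(rep(c("A", "B"), 10), cell_ids(em3))
  nd3 <- compute_min_knn_distance(em3, lab, k = 3)
  for (i in seq_len(nrow(nd3))) {
    expect_false(nd3$cell_id[i] %in% nd3$neighbor_ids[[i]])
    expect_true(all(lab[nd3$neighbor_ids[[i]]] == nd3$cluster[i]))
  }
})

test_that("small clusters reduce k and singletons get an Inf sentinel", {
  em <- as_lognorm(matrix(c(0, 1, 2, 10), 1, 4))
  lab <- setNames(c("A", "A", "A", "B"), cell_ids(em))
  expect_warning(nd <- compute_min_knn_distance(em, lab, k = 30),
                 "singleton")
  expect_equal(nd$k_eff[nd$cluster == "A"], rep(2L, 3))
  expect_equal(nd$min_dist[nd$cluster == "B"], Inf)
  suppressWarnings(tr <- trim_cells(nd, alpha = 0.3))
  expect_equal(as.character(tr$flag[tr$cluster == "B"]), "core")
  expect_error(compute_min_knn_distance(em, lab, k = 0), "positive")
  expect_error(compute_min_knn_distance(em, lab[-1]), "without a cluster")
})

test_that("quantile trimming flags exactly the cells above the type-7 cutoff", {
  em <- as_lognorm(matrix(1:10, 1, 10))
  nd <- compute_min_knn_distance(em, one_cluster(em), k = 1)
  # alpha = 0 flags nothing
  tr0 <- trim_cells(nd, 0)
  expect_equal(sum(tr0$flag == "extreme"), 0L)
  expect_error(trim_cells(nd, 1), "alpha")
  expect_error(trim_cells(nd, -0.1), "alpha")
})

test_that("threshold and flags reproduce the enumeration oracle on 1..10", {
  nd <- tibble::tibble(cell_id = sprintf("c%d", 1:10),
                       cluster = factor(rep("A", 10)),
                       min_dist = as.numeric(1:10))
  tr <- trim_cells(nd, alpha = 0.2)
  expect_equal(tr$threshold, rep(8.2, 10))
  expect_setequal(tr$cell_id[tr$flag == "extreme"], c("c9", "c10"))
})

test_that("exact 10% of distinct-valued cells are flagged at alpha = 0.1", {
  set.seed(41)
  md <- sample(seq(0.01, 1, length.out = 100))
  nd <- tibble::tibble(cell_id = sprintf("c%d", 1:100),
                       cluster = factor(rep("A", 100)), min_dist = md)
  tr <- trim_cells(nd, alpha = 0.1)
  expect_equal(sum(tr$flag == "extreme"), 10L)
  expect_setequal(tr$cell_id[tr$flag == "extreme"],
                  nd$cell_id[order(-nd$min_dist)[1:10]])
})

test_that("min distances equal the brute-force pairwise oracle exactly", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(5:60, 1); p <- sample(2:50, 1)
    em <- as_lognorm(matrix(abs(rnorm(n * p)), p, n))
    lab <- setNames(sample(c("A", "B"), n, replace = TRUE), cell_ids(em))
    if (min(table(lab)) < 2) lab[] <- "A"
    nd <- compute_min_knn_distance(em, lab, k = sample(1:8, 1))
    bf <- brute_min_dist(em, lab)
    expect_true(all(nd$min_dist == bf[nd$cell_id]))
  }
})

test_that("flagged sets are nested in alpha", {
  set.seed(13)
  nd <- tibble::tibble(cell_id = sprintf("c%d", 1:80),
                       cluster = factor(rep(c("A", "B"), 40)),
                       min_dist = rexp(80))
  prev <- character()
  for (a in seq(0.05, 0.4, by = 0.05)) {
    cur <- with(trim_cells(nd, a), cell_id[flag == "extreme"])
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("distances are isometry-invariant and scale-equivariant", {
  set.seed(19)
  x <- matrix(rnorm(30 * 5), 5, 30)
  em <- as_lognorm(x)
  lab <- one_cluster(em)
  nd <- compute_min_knn_distance(em, lab, k = 4)
  # translation
  em_t <- as_lognorm(x + 3)
  nd_t <- compute_min_knn_distance(em_t, lab, k = 4)
  expect_equal(nd_t$min_dist, nd$min_dist, tolerance = 1e-9)
  # orthogonal rotation of feature space
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  em_r <- as_lognorm(q %*% x)
  nd_r <- compute_min_knn_distance(em_r, lab, k = 4)
  expect_equal(nd_r$min_dist, nd$min_dist, tolerance = 1e-9)
  # scaling
  em_s <- as_lognorm(2.5 * x)
  nd_s <- compute_min_knn_distance(em_s, lab, k = 4)
  expect_equal(nd_s$min_dist, 2.5 * nd$min_dist, tolerance = 1e-9)
  tr <- trim_cells(nd, 0.2); tr_s <- trim_cells(nd_s, 0.2)
  expect_identical(tr$flag, tr_s$flag)
})

test_that("trim_dist composes trimming and matches the alpha call path", {
  pd <- gen_planted_dataset(seed = 3, n_clusters = 2,
                            cells_per_cluster = 40, n_genes = 100,
                            fragile = FALSE)
  nm <- log_normalize(pd$counts)
  # keep_frac = 1 returns the input unchanged
  td1 <- trim_dist(nm, pd$labels, knn_k = 10, keep_frac = 1)
  expect_equal(dim(td1$matrix), dim(nm))
  # keep_frac = 0.9 is alpha = 0.1
  td <- trim_dist(nm, pd$labels, knn_k = 10, keep_frac = 0.9)
  nd <- compute_min_knn_distance(nm, pd$labels, k = 10)
  tr <- trim_cells(nd, alpha = 0.1)
  expect_identical(td$result$flag, tr$flag)
  expect_equal(ncol(td$matrix$values),
               sum(tr$flag == "core"))
  expect_error(trim_dist(nm, pd$labels, keep_frac = 0), "keep_frac")
})

test_that("trimming recovers planted border cells above chance", {
  pd <- gen_planted_dataset(seed = 2)
  nm <- log_normalize(pd$counts)
  td <- trim_dist(nm, pd$labels, knn_k = 15, keep_frac = 0.9)
  removed <- td$result$cell_id[td$result$flag == "extreme"]
  border <- pd$truth$cell_id[pd$truth$is_border]
  precision <- length(intersect(removed, border)) / length(removed)
  # chance level = planted fraction (0.1)
  expect_gt(precision, 0.1)
})
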