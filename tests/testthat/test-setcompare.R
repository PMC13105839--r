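mk <- function(cl, genes) tibble::tibble(cluster = cl, gene = genes)

test_that("set comparison follows the P1/P2/P3 formulas", {
  # identical sets
  sc <- compare_marker_sets(mk("A", letters[1:5]), mk("A", letters[1:5]))
  expect_equal(c(sc$p1, sc$p2, sc$p3), c(0, 100, 0))
  # disjoint sets of sizes 3 and 2
  sc2 <- compare_marker_sets(mk("A", c("a", "b", "c")), mk("A", c("d", "e")))
  expect_equal(sc2$m, 5L)
  expect_equal(c(sc2$p1, sc2$p2, sc2$p3), c(60, 0, 40))
  # partial overlap
  sc3 <- compare_marker_sets(mk("A", c("a", "b", "c")),
                             mk("A", c("b", "c", "d")))
  expect_equal(sc3$m, 4L)
  expect_equal(c(sc3$p1, sc3$p2, sc3$p3), c(25, 50, 25))
  expect_equal(sort(unlist(sc3$genes_s2)), c("b", "c"))
  expect_equal(unlist(sc3$genes_s1), "a")
  expect_equal(unlist(sc3$genes_s3), "d")
})

test_that("empty unions and one-sided clusters are handled", {
  expect_warning(
    sc <- compare_marker_sets(mk(character(), character()),
                              mk("A", c("x", "y"))),
    "only one")
  expect_equal(sc$p3, 100)
  expect_warning(
    sc2 <- compare_marker_sets(mk("A", "a"), mk("B", "b")),
    "only one")
  expect_equal(sc2$p1[sc2$cluster == "A"], 100)
  expect_equal(sc2$p3[sc2$cluster == "B"], 100)
  # m = 0: proportions all zero, flagged empty
  suppressWarnings(
    sc3 <- compare_marker_sets(mk("A", "a"), mk(c("A", "B"), c("a", "b"))))
  expect_false(any(sc3$empty))
  empty_a <- tibble::tibble(cluster = factor(character(), levels = "A"),
                            gene = character())
  sc4 <- compare_marker_sets(empty_a, empty_a)
  expect_true(sc4$empty)
  expect_equal(c(sc4$p1, sc4$p2, sc4$p3), c(0, 0, 0))
})

test_that("proportions sum to 100 and swap antisymmetrically on random pairs", {
  set.seed(55)
  for (i in 1:200) {
    u <- sprintf("gene%d", 1:30)
    sf <- sample(u, rpois(1, 8))
    st <- sample(u, rpois(1, 8))
    a <- compare_marker_sets(mk("X", sf), mk("X", st))
    if (!a$empty) expect_equal(a$p1 + a$p2 + a$p3, 100, tolerance = 1e-12)
    b <- compare_marker_sets(mk("X", st), mk("X", sf))
    expect_equal(a$p1, b$p3)
    expect_equal(a$p2, b$p2)
    expect_equal(a$p3, b$p1)
    # relabelling genes leaves the statistics unchanged
    map <- setNames(sprintf("z%d", 1:30), u)
    c_ <- compare_marker_sets(mk("X", unname(map[sf])),
                              mk("X", unname(map[st])))
    expect_equal(c(a$p1, a$p2, a$p3), c(c_$p1, c_$p2, c_$p3))
  }
})

test_that("tidy() emits the heatmap-ready long table", {
  sc <- compare_marker_sets(mk("A", c("a", "b", "c")),
                            mk("A", c("b", "c", "d")))
  long <- tidy(sc)
  expect_equal(nrow(long), 3L)
  expect_setequal(as.character(long$category), c("S1", "S2", "S3"))
  expect_equal(long$pct[long$category == "S2"], 50)
  expect_equal(long$count[long$category == "S1"], 1L)
  expect_true(all(c("n_full", "n_trim") %in% names(long)))
})

test_that("identical variants produce identical comparison blocks", {
  pd <- gen_planted_dataset(seed = 6, n_clusters = 2,
                            cells_per_cluster = 40, n_genes = 120,
                            fragile = FALSE)
  va <- list(norm = "lognorm", n_hvg = 50, label = "a")
  vb <- list(norm = "lognorm", n_hvg = 50, label = "b")
  te <- trim_effect(pd$counts, pd$labels, variant_a = va, variant_b = vb,
                    knn_k = 10, keep_frac = 0.9)
  a <- tibble::as_tibble(unclass(te$comparisons[[1]]))
  b <- tibble::as_tibble(unclass(te$comparisons[[2]]))
  expect_equal(a, b)
  expect_s3_class(tidy(te), "tbl_df")
  expect_setequal(levels(tidy(te)$variant), c("a", "b"))
})

test_that("robust clusters stay intact and fragile markers land in S1", {
  pd <- gen_planted_dataset(seed = 1)
  nm <- log_normalize(pd$counts)
  td <- trim_dist(nm, pd$labels, knn_k = 15, keep_frac = 0.9)
  keep <- td$result$cell_id[td$result$flag == "core"]
  full <- find_all_markers(nm, pd$labels)
  trimmed <- find_all_markers(
    subset_expr(nm, cells = keep),
    pd$labels[pd$labels$cell_id %in% keep, ])
  sc <- compare_marker_sets(full, trimmed)
  expect_gte(min(sc$p2), 75)          # planted robust markers dominate
  frag <- pd$marker_design$gene[pd$marker_design$type == "fragile"]
  expect_true(all(frag %in% full$gene))
  expect_true(all(frag %in% unlist(sc$genes_s1)))
  expect_true(all(sc$p1 > 0))
})

test_that("breakdown profile starts at 100 and tracks marker loss", {
  pd <- gen_planted_dataset(seed = 9, n_clusters = 2,
                            cells_per_cluster = 50, n_genes = 150)
  bp <- breakdown_profile(pd$counts, pd$labels,
                          levels = c(0, 0.1, 0.3), n_hvg = 80, knn_k = 10)
  expect_true(all(bp$retention[bp$level == 0 & bp$n_full > 0] == 100))
  expect_true(all(bp$retention >= 0 & bp$retention <= 100, na.rm = TRUE))
  expect_error(breakdown_profile(pd$counts, pd$labels,
                                 levels = c(0.1, 0.2)), "starting at 0")
  expect_error(breakdown_profile(pd$counts, pd$labels,
                                 levels = c(0, 0.5, 0.3)), "ascending")
})
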