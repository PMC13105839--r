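square_pts <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE,
         dimnames = list(sprintf("c%d", 1:4), NULL))
}

test_that("large hull_alpha recovers the convex hull of a square", {
  pts <- square_pts()
  lab <- setNames(rep("A", 4), rownames(pts))
  h <- compute_alpha_hull(pts, lab, hull_alpha = 100)
  expect_equal(nrow(h$A$edges), 4L)
  # perimeter 4, area 1
  per <- sum(apply(h$A$edges, 1, function(e)
    sqrt(sum((h$A$points[e[1], ] - h$A$points[e[2], ])^2))))
  expect_equal(per, 4)
  expect_equal(hull_area(h$A), 1)
  expect_error(compute_alpha_hull(pts, lab, hull_alpha = 0), "positive")
})

test_that("smaller hull_alpha gives a tighter (concave) boundary", {
  pts <- square_pts()
  lab <- setNames(rep("A", 4), rownames(pts))
  # smallest admissible radius still covering the square's edges
  h_small <- compute_alpha_hull(pts, lab, hull_alpha = 0.72)
  h_large <- compute_alpha_hull(pts, lab, hull_alpha = 100)
  expect_lte(hull_area(h_small$A), hull_area(h_large$A))

  # C-shaped cloud: alpha hull is much tighter than the convex hull
  set.seed(3)
  th <- runif(40, pi / 4, 7 * pi / 4)
  cp <- cbind(cos(th), sin(th)) + matrix(rnorm(80, 0, 0.05), ncol = 2)
  rownames(cp) <- sprintf("p%d", 1:40)
  labc <- setNames(rep("C", 40), rownames(cp))
  hs <- compute_alpha_hull(cp, labc, hull_alpha = 0.35)
  ch <- chull(cp)
  v <- cp[ch, ]
  convex_area <- abs(sum(v[, 1] * v[c(2:nrow(v), 1), 2] -
                           v[c(2:nrow(v), 1), 1] * v[, 2])) / 2
  expect_lt(hull_area(hs$C), convex_area)
})

test_that("degenerate clusters fall back to convex-hull primitives", {
  pts <- rbind(a = c(0, 0), b = c(1, 1))
  lab <- setNames(rep("L", 2), rownames(pts))
  expect_warning(h <- compute_alpha_hull(pts, lab, 1), "degenerate")
  expect_equal(nrow(h$L$edges), 1L)
  d <- suppressWarnings(
    distance_to_hull(pts, compute_alpha_hull(pts, lab, 1), lab))
  expect_equal(d$dist_to_hull, c(0, 0))
  # collinear triple
  pts3 <- rbind(a = c(0, 0), b = c(1, 1), c = c(2, 2))
  lab3 <- setNames(rep("L", 3), rownames(pts3))
  expect_warning(compute_alpha_hull(pts3, lab3, 1), "degenerate")
  # non-finite coordinates refuse
  ptsn <- rbind(a = c(0, 0), b = c(NA, 1), c = c(2, 2))
  expect_error(suppressWarnings(
    compute_alpha_hull(ptsn, setNames(rep("L", 3), rownames(ptsn)), 1)))
})

test_that("distance to hull matches geometry and a dense-sampling oracle", {
  pts <- rbind(square_pts(), c5 = c(0.5, 0.5))
  lab <- setNames(rep("A", 5), rownames(pts))
  h <- compute_alpha_hull(pts, lab, hull_alpha = 100)
  d <- distance_to_hull(pts, h, lab)
  expect_equal(d$dist_to_hull[1:4], rep(0, 4))       # vertices
  expect_equal(d$dist_to_hull[5], 0.5)               # centre of unit square

  # random convex polygon, interior points vs dense boundary discretization
  set.seed(8)
  ang <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(cos(ang), sin(ang)) * runif(12, 1.5, 2)
  rownames(poly) <- sprintf("v%d", 1:12)
  inner <- matrix(runif(60, -0.5, 0.5), ncol = 2)
  rownames(inner) <- sprintf("i%d", 1:30)
  all_pts <- rbind(poly, inner)
  lab2 <- setNames(rep("P", nrow(all_pts)), rownames(all_pts))
  h2 <- compute_alpha_hull(all_pts, lab2, hull_alpha = 1000)
  d2 <- distance_to_hull(all_pts, h2, lab2)
  # oracle: 1e4 points sampled along each boundary edge
  hull <- h2$P
  bnd <- do.call(rbind, lapply(seq_len(nrow(hull$edges)), function(e) {
    a <- hull$points[hull$edges[e, 1], ]
    b <- hull$points[hull$edges[e, 2], ]
    t <- seq(0, 1, length.out = ceiling(1e4 / nrow(hull$edges)))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  for (i in seq_len(30)) {
    p <- inner[i, ]
    oracle <- min(sqrt((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2))
    expect_equal(d2$dist_to_hull[d2$cell_id == rownames(inner)[i]],
                 oracle, tolerance = 1e-3)
  }
})

test_that("hull trimming flags strictly below the type-7 quantile", {
  # synthetic distances 1..10 via a constructed star-shaped cluster are
  # unwieldy; check the quantile rule directly on trim_hull's output scale
  set.seed(21)
  pts <- matrix(rnorm(200), ncol = 2)
  rownames(pts) <- sprintf("c%d", 1:100)
  lab <- setNames(rep("A", 100), rownames(pts))
  expect_error(trim_hull(pts, lab, 1, outlier_quantile = 1.2), "quantile")
  t0 <- trim_hull(pts, lab, hull_alpha = 5, outlier_quantile = 0)
  expect_equal(sum(t0$flag == "extreme"), 0L)
  t3 <- trim_hull(pts, lab, hull_alpha = 5, outlier_quantile = 0.3)
  thr <- stats::quantile(t3$dist_to_hull, 0.3, type = 7, names = FALSE)
  expect_equal(t3$threshold[1], thr)
  expect_setequal(t3$cell_id[t3$flag == "extreme"],
                  t3$cell_id[t3$dist_to_hull < thr])
  # boundary cells are flagged whenever the threshold is positive
  expect_true(all(t3$flag[t3$dist_to_hull == 0] == "extreme"))
})

test_that("hull flags are nested in the quantile and rigid-motion invariant", {
  set.seed(9)
  pts <- matrix(rnorm(120), ncol = 2)
  rownames(pts) <- sprintf("x%d", 1:60)
  lab <- setNames(rep(c("A", "B"), each = 30), rownames(pts))
  e1 <- with(trim_hull(pts, lab, 3, 0.2), cell_id[flag == "extreme"])
  e2 <- with(trim_hull(pts, lab, 3, 0.4), cell_id[flag == "extreme"])
  expect_true(all(e1 %in% e2))

  # rotation + translation leave distances unchanged
  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts_r <- sweep(pts %*% rot, 2, c(-7, 11), "+")
  rownames(pts_r) <- rownames(pts)
  a <- trim_hull(pts, lab, 3, 0.3)
  b <- trim_hull(pts_r, lab, 3, 0.3)
  expect_equal(b$dist_to_hull, a$dist_to_hull, tolerance = 1e-9)
  expect_identical(b$flag, a$flag)
})

test_that("convex clouds at large hull_alpha agree with a convex-hull oracle", {
  set.seed(33)
  pts <- matrix(rnorm(160), ncol = 2)
  rownames(pts) <- sprintf("c%d", 1:80)
  lab <- setNames(rep("A", 80), rownames(pts))
  tr <- trim_hull(pts, lab, hull_alpha = 1e3, outlier_quantile = 0.25)
  # oracle: distances to the convex hull boundary segments
  ch <- chull(pts)
  seg <- cbind(ch, c(ch[-1], ch[1]))
  od <- vapply(seq_len(80), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(seg)), function(s) {
      a <- pts[seg[s, 1], ]; b <- pts[seg[s, 2], ]
      ab <- b - a
      t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((p - a - t * ab)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tr$dist_to_hull, od, tolerance = 1e-9)
})
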