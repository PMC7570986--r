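test_that("confidence ellipse center, covariance and Student scale", {
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(0, 0))
  e <- confidence_ellipse(pts, level = 0.80)
  expect_equal(e$center, c(0, 0))
  expect_equal(e$cov, diag(2) * 0.5, tolerance = 1e-12)
  # frozen from the Student-quantile oracle qt(0.9, 4)^2
  expect_equal(e$scale2, 2.350721, tolerance = 1e-5)
  expect_equal(e$scale2, stats::qt(0.9, 4)^2)
  # hotelling mean-region alternative is smaller
  eh <- confidence_ellipse(pts, level = 0.80, method = "hotelling")
  expect_lt(eh$scale2, e$scale2)
  expect_equal(eh$scale2, 2 * 4 / (5 * 3) * stats::qf(0.8, 2, 3))
})

test_that("degenerate replicate clouds are rejected", {
  expect_error(confidence_ellipse(rbind(c(0, 0), c(1, 1)), 0.8), ">= 3")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(confidence_ellipse(coll, 0.8), "singular covariance")
})

test_that("Mahalanobis distance has its closed forms", {
  e <- make_ellipse(c(0, 0), diag(2), 1)
  expect_equal(mahalanobis_distance(c(0, 0), e), 0)
  expect_equal(mahalanobis_distance(c(1, 0), e), 1)
  e2 <- make_ellipse(c(0, 0), diag(c(4, 1)), 1)
  expect_equal(mahalanobis_distance(c(2, 0), e2), 1)   # 2 / sqrt(4)
  # labelled point-set interface
  set.seed(1)
  pts <- matrix(rnorm(20), 10, 2)
  expect_equal(mahalanobis_distance(colMeans(pts), pts), 0, tolerance = 1e-12)
})

test_that("intersection points hit the closed-form cases", {
  # disjoint unit circles
  expect_equal(nrow(ellipse_intersection_points(circle(0, 0, 1), circle(5, 0, 1))), 0L)
  # unit circles at distance 1: (0.5, +/- sqrt(3)/2)
  p <- ellipse_intersection_points(circle(0, 0, 1), circle(1, 0, 1))
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p[, 2]), c(-sqrt(3) / 2, sqrt(3) / 2), tolerance = 1e-9)
  expect_equal(p[, 1], c(0.5, 0.5), tolerance = 1e-9, ignore_attr = TRUE)
  # concentric axis-aligned ellipses with swapped semi-axes: 4 symmetric points
  e1 <- make_ellipse(c(0, 0), diag(c(9, 1)), 1)
  e2 <- make_ellipse(c(0, 0), diag(c(1, 9)), 1)
  p4 <- ellipse_intersection_points(e1, e2)
  expect_equal(nrow(p4), 4L)
  expect_equal(sort(abs(p4[, 1])), rep(sqrt(0.9), 4), tolerance = 1e-9)
  expect_equal(sort(abs(p4[, 2])), rep(sqrt(0.9), 4), tolerance = 1e-9)
})

test_that("pair crossing numbers encode containment, disjointness and tangency", {
  nested <- pair_crossing_number(circle(0, 0, 1), circle(0, 0, 3))
  expect_true(nested$containment)
  expect_equal(nested$crossing_number, 4L)
  expect_equal(nested$n_boundary_points, 0L)

  expect_equal(pair_crossing_number(circle(0, 0, 1), circle(5, 0, 1))$crossing_number, 0L)
  expect_equal(pair_crossing_number(circle(0, 0, 1), circle(1, 0, 1))$crossing_number, 2L)
  # coincident ellipses classify as containment
  expect_equal(pair_crossing_number(circle(2, 1, 1), circle(2, 1, 1))$crossing_number, 4L)
  # external tangency counts as a double crossing
  expect_equal(pair_crossing_number(circle(0, 0, 1), circle(2, 0, 1))$crossing_number, 2L)
})

test_that("total CrN sums pairs; tangency follows the double-count rule", {
  disjoint <- list(circle(0, 0, 1), circle(5, 0, 1), circle(10, 0, 1))
  expect_equal(total_crossing_number(disjoint), 0L)
  nested_far <- list(circle(0, 0, 1), circle(0, 0, 3), circle(50, 0, 1))
  expect_equal(total_crossing_number(nested_far), 4L)
  # chain of unit circles at 0, 1, 2: two transversal pairs (2 each) plus one
  # externally tangent pair (2)
  chain <- list(circle(0, 0, 1), circle(1, 0, 1), circle(2, 0, 1))
  expect_equal(total_crossing_number(chain), 6L)
})

test_that("quartic intersections agree with the dense boundary-sampling oracle", {
  set.seed(101)
  n_pairs <- 300
  for (i in seq_len(n_pairs)) {
    a <- random_ellipse()
    b <- random_ellipse()
    pts <- ellipse_intersection_points(a, b)
    counted <- oracle_crossings(a, b)
    if (nrow(pts) != counted) counted <- oracle_crossings(a, b, m = 65536)
    expect_equal(nrow(pts), counted,
                 info = sprintf("random pair %d", i))
    if (nrow(pts) > 0) {
      resid <- max(abs(ellipse_form(a, pts)), abs(ellipse_form(b, pts)))
      expect_lt(resid, 1e-6)
    }
  }
})

test_that("total CrN is invariant under rigid motions of the score plane", {
  set.seed(7)
  ells <- replicate(5, random_ellipse(), simplify = FALSE)
  base <- total_crossing_number(ells)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(4.2, -1.3)
  moved <- lapply(ells, function(e)
    make_ellipse(as.numeric(R %*% e$center) + shift, R %*% e$cov %*% t(R), e$scale2))
  expect_equal(total_crossing_number(moved), base)
})

test_that("group counting merges transitively and is monotone under shrinking", {
  disjoint <- list(circle(0, 0, 1, "a"), circle(5, 0, 1, "b"), circle(10, 0, 1, "c"))
  expect_equal(count_groups(disjoint), 3L)
  allhit <- list(circle(0, 0, 2, "a"), circle(1, 0, 2, "b"), circle(2, 0, 2, "c"))
  expect_equal(count_groups(allhit), 1L)
  # chain A-B, B-C crossing, A-C disjoint: one group by transitivity
  chain <- list(circle(0, 0, 1.2, "a"), circle(2, 0, 1.2, "b"), circle(4, 0, 1.2, "c"))
  expect_equal(count_groups(chain), 1L)
  # shrinking every ellipse never decreases the number of groups
  set.seed(21)
  for (rep in 1:20) {
    ells <- replicate(4, random_ellipse(), simplify = FALSE)
    g1 <- count_groups(ells)
    shrunk <- lapply(ells, function(e) make_ellipse(e$center, e$cov, e$scale2 * 0.5))
    expect_gte(count_groups(shrunk), g1)
  }
})

test_that("the Mahalanobis-distance separation predicate is available", {
  pts_a <- rbind(c(0, 0), c(0.2, 0.1), c(-0.2, -0.1), c(0.1, -0.2), c(-0.1, 0.2))
  pts_b <- pts_a + 10   # far apart
  ea <- confidence_ellipse(pts_a, sample_id = "a")
  eb <- confidence_ellipse(pts_b, sample_id = "b")
  expect_equal(count_groups(list(ea, eb), predicate = "mahalanobis"), 2L)
  ec <- confidence_ellipse(pts_a + 0.05, sample_id = "c")
  expect_equal(count_groups(list(ea, ec), predicate = "mahalanobis"), 1L)
})

test_that("zero crossings coincide with disjoint regions (rasterization oracle)", {
  set.seed(33)
  for (rep in 1:25) {
    a <- random_ellipse()
    b <- random_ellipse()
    pc <- pair_crossing_number(a, b)
    # rasterize a bounding box; regions overlap iff some cell is in both
    lo <- pmin(a$center, b$center) - 6
    hi <- pmax(a$center, b$center) + 6
    gx <- seq(lo[1], hi[1], length.out = 130)
    gy <- seq(lo[2], hi[2], length.out = 130)
    grid <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
    ina <- stats::mahalanobis(grid, a$center, a$cov) <= a$scale2
    inb <- stats::mahalanobis(grid, b$center, b$cov) <= b$scale2
    overlap <- any(ina & inb)
    expect_equal(pc$crossing_number == 0L, !overlap,
                 info = sprintf("raster pair %d", rep))
  }
})
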