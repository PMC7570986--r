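test_that("total sensitivity is 1 for well-separated tight clusters", {
  set.seed(20)
  a <- matrix(rnorm(10, sd = 0.5), 5, 2)
  b <- matrix(rnorm(10, sd = 0.5), 5, 2) + 100
  ts <- total_sensitivity(rbind(a, b), labels = rep(c("A", "B"), each = 5))
  expect_equal(ts$ts, 1)
  expect_true(all(ts$table$status == "correct"))
  # own replicate at the class center has D_M = 0 to its class
  expect_lt(min(ts$distances[1:5, "A"]), 4)
})

test_that("a deliberately ambiguous well is flagged multi-class", {
  fx <- ambiguous_fixture()
  ts <- total_sensitivity(fx$scores, labels = fx$labels, threshold = 4)
  expect_equal(ts$ts, 9 / 10)
  expect_equal(ts$table$status[5], "multi-class")
  expect_equal(sum(ts$table$status == "multi-class"), 1L)
  expect_setequal(strsplit(ts$table$matched_classes[5], ";")[[1]], c("A", "B"))
  # both distances really are within the membership bound
  expect_true(all(ts$distances[5, ] <= 4))
})

test_that("total sensitivity is invariant under affine maps of score space", {
  set.seed(22)
  x <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2) + 3,
             matrix(rnorm(10), 5, 2) + c(0, 6))
  lab <- rep(c("A", "B", "C"), each = 5)
  base <- total_sensitivity(x, lab)$ts
  for (rep in 1:5) {
    A <- matrix(rnorm(4), 2)
    while (abs(det(A)) < 0.2) A <- matrix(rnorm(4), 2)
    y <- x %*% t(A) + matrix(rnorm(2), nrow(x), 2, byrow = TRUE)
    expect_equal(total_sensitivity(y, lab)$ts, base)
  }
})

test_that("leave-one-out variant is at most as generous as training TS", {
  set.seed(23)
  x <- rbind(matrix(rnorm(12, sd = 1.5), 6, 2), matrix(rnorm(12, sd = 1.5), 6, 2) + 4)
  lab <- rep(c("A", "B"), each = 6)
  expect_lte(total_sensitivity(x, lab, loo = TRUE)$ts,
             total_sensitivity(x, lab)$ts + 1e-12)
})

test_that("QDA equals the Mahalanobis rule when class covariances are equal", {
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(0.5, 0.5))
  shift <- matrix(c(4, 1), 5, 2, byrow = TRUE)
  x <- rbind(offs, offs + shift)   # identical sample covariance by construction
  lab <- rep(c("A", "B"), each = 5)
  q <- qda_sensitivity(x, lab)
  # oracle: nearest class by Mahalanobis with the shared covariance
  S <- stats::cov(offs)
  dA <- stats::mahalanobis(x, colMeans(offs), S)
  dB <- stats::mahalanobis(x, colMeans(offs) + c(4, 1), S)
  oracle <- ifelse(dA <= dB, "A", "B")
  expect_equal(q$assigned, oracle)
  expect_equal(q$sensitivity, mean(oracle == lab))
})

test_that("QDA respects mirror symmetry and agrees with the MASS reference", {
  set.seed(25)
  right <- cbind(abs(rnorm(20, 2)), rnorm(20))
  left <- -right + cbind(0, rnorm(20, sd = 1e-6))  # mirrored about the y-axis
  x <- rbind(right, left)
  lab <- rep(c("R", "L"), each = 20)
  q <- qda_sensitivity(x, lab)
  expect_equal(q$sensitivity, 1)

  skip_if_not_installed("MASS")
  set.seed(26)
  x2 <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, sd = 2), 20, 2) + 1.5)
  lab2 <- rep(c("A", "B"), each = 20)
  fit <- MASS::qda(x2, grouping = factor(lab2))
  ref <- as.character(stats::predict(fit, x2)$class)
  expect_equal(qda_sensitivity(x2, lab2)$assigned, ref)
})

test_that("SVM sensitivities behave as the kernels predict", {
  set.seed(27)
  a <- matrix(rnorm(20, sd = 0.3), 10, 2)
  b <- matrix(rnorm(20, sd = 0.3), 10, 2) + 5
  x <- rbind(a, b); lab <- rep(c("A", "B"), each = 10)
  expect_equal(svm_sensitivity(x, lab, kernel = "linear"), 1)

  # XOR pattern: RBF beats the linear kernel
  xor <- rbind(
    matrix(rnorm(40, sd = 0.2), 20, 2) + matrix(c(1, 1), 20, 2, byrow = TRUE) *
      rep(c(1, -1), each = 10),
    cbind(rnorm(20, rep(c(1, -1), each = 10), 0.2),
          rnorm(20, rep(c(-1, 1), each = 10), 0.2))
  )
  lab_xor <- rep(c("P", "Q"), each = 20)
  s_rbf <- svm_sensitivity(xor, lab_xor, kernel = "rbf")
  s_lin <- svm_sensitivity(xor, lab_xor, kernel = "linear")
  expect_gt(s_rbf, s_lin)
  expect_error(svm_sensitivity(x, lab, kernel = "sigmoid"), "unknown kernel")

  # indistinguishable classes hover near chance
  set.seed(28)
  z <- matrix(rnorm(40), 20, 2)
  s_same <- svm_sensitivity(rbind(z, z), rep(c("A", "B"), each = 20), kernel = "linear")
  expect_lte(s_same, 0.75)
})

test_that("metric correlations reproduce hand-computed Pearson values", {
  report <- data.frame(
    condition = c("w", "x", "y", "z"),
    n_groups = c(4, 3, 2, 1),
    crn = c(0, 10, 20, 30),
    rp = c(8, 6, 4, 2),
    ts_mah = c(1, 0.9, 0.8, 0.7),
    ts_qda = c(0.5, 0.5, 0.5, 0.5)   # zero variance
  )
  cm <- metric_correlations(report)
  expect_equal(cm["n_groups", "rp"], 1)
  expect_equal(cm["crn", "rp"], -1)
  expect_equal(cm["crn", "ts_mah"],
               stats::cor(c(0, 10, 20, 30), c(1, 0.9, 0.8, 0.7)))
  expect_true(all(is.na(cm["ts_qda", setdiff(colnames(cm), "ts_qda")])))
  expect_error(metric_correlations(report[1:2, ]), ">= 3 conditions")
})

test_that("rank-sum rating rewards the unanimous winner and averages ties", {
  report <- data.frame(
    condition = c("A", "B", "C"),
    crn = c(5, 10, 20),       # lower better: A first
    rp = c(9, 4, 1),          # higher better: A first
    ts_mah = c(1.0, 0.8, 0.6) # higher better: A first
  )
  rated <- overall_rating(report)
  expect_equal(rated$condition[1], "A")
  expect_equal(rated$rating[rated$condition == "A"], 3)  # 3 metrics, all rank 1
  expect_equal(rated$rating[rated$condition == "C"], 9)

  # tie on one metric -> shared mean rank 1.5
  r2 <- data.frame(condition = c("A", "B"), crn = c(7, 7), rp = c(2, 1))
  rated2 <- overall_rating(r2)
  expect_equal(rated2$rank_crn, c(1.5, 1.5), ignore_attr = TRUE)

  # arithmetic example: places A (1,2), B (2,1), C (3,3)
  r3 <- data.frame(
    condition = c("A", "B", "C"),
    crn = c(1, 2, 3),          # lower better: places 1, 2, 3
    rp = c(5, 6, 1)            # higher better: places 2, 1, 3
  )
  rated3 <- overall_rating(r3)
  expect_equal(rated3$rating[match(c("A", "B", "C"), rated3$condition)], c(3, 3, 6))
  expect_equal(rated3$condition[3], "C")
  # invariance to row order; ties broken by condition name
  rated3r <- overall_rating(r3[c(3, 1, 2), ])
  expect_equal(rated3r$condition, rated3$condition)
  expect_equal(rated3$condition[1:2], c("A", "B"))
})
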