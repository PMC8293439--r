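test_that("subset R2 matches a normal-equations hand computation", {
  # 6-point dataset solved via the normal equations, independently of lm
  y <- c(1.0, 2.1, 2.9, 4.2, 4.8, 6.1)
  X <- cbind(x1 = c(1, 2, 3, 4, 5, 6), x2 = c(2, 1, 4, 3, 6, 5))
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  res <- y - Z %*% beta
  r2_hand <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(subset_r2(y, X, c(1, 2)), r2_hand, tolerance = 1e-12)
  expect_equal(subset_r2(X[, 1], X, 1), 1)      # y identical to x1
  set.seed(18)
  noise <- rnorm(1000)
  expect_lt(subset_r2(noise, matrix(rnorm(3000), 1000, 3), 1:3), 0.01)
  expect_error(subset_r2(y, cbind(X, x3 = X[, 1] * 2), c(1, 3)), "singular|collinear")
  expect_error(subset_r2(y, cbind(X, k = rep(1, 6)), 3), "constant")
})

test_that("orthogonal predictors yield purely unique components", {
  set.seed(19)
  raw <- matrix(rnorm(3000), 1000, 3)
  X <- qr.Q(qr(raw))                # exactly orthogonal columns
  y <- 0.8 * X[, 1] + 0.5 * X[, 2] + 0.2 * X[, 3] + rnorm(1000, 0, 0.02)
  cm <- suppressWarnings(commonality(y, X[, 1], X[, 2], X[, 3],
                                     labels = c("A", "B", "C")))
  expect_lt(max(abs(c(cm$shared_pairwise, cm$shared_all))), 1e-3)
  r2_single <- sapply(1:3, function(j) cor(y, X[, j])^2)
  expect_equal(unname(cm$unique), r2_single, tolerance = 2e-3)
})

test_that("components match a brute-force subset-regression oracle", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 300
    z <- rnorm(n)
    x1 <- z + rnorm(n); x2 <- 0.5 * z + rnorm(n); x3 <- rnorm(n) + 0.3 * x1
    y <- x1 + x2 + 0.5 * x3 + rnorm(n, 0, 2)
    cm <- suppressWarnings(commonality(y, x1, x2, x3,
                                       labels = c("A", "B", "C")))
    # oracle: all seven R2 values via lm(), assembled independently
    r2 <- function(fml) summary(lm(fml))$r.squared
    rA <- r2(y ~ x1); rB <- r2(y ~ x2); rC <- r2(y ~ x3)
    rAB <- r2(y ~ x1 + x2); rAC <- r2(y ~ x1 + x3); rBC <- r2(y ~ x2 + x3)
    rABC <- r2(y ~ x1 + x2 + x3)
    expect_equal(unname(cm$unique),
                 c(rABC - rBC, rABC - rAC, rABC - rAB), tolerance = 1e-10)
    expect_equal(unname(cm$shared_pairwise),
                 c(rAC + rBC - rABC - rC,
                   rAB + rBC - rABC - rB,
                   rAB + rAC - rABC - rA), tolerance = 1e-10)
    expect_equal(cm$shared_all,
                 rA + rB + rC - rAB - rAC - rBC + rABC, tolerance = 1e-10)
    expect_equal(cm$r2_full, rABC, tolerance = 1e-12)
  }
})

test_that("the decomposition sums to the full R2 and respects invariances", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3) %*% matrix(rnorm(9, sd = 0.6), 3, 3)
    X <- X + matrix(rnorm(n * 3), n, 3)
    y <- X %*% rnorm(3) + rnorm(n)
    cm <- suppressWarnings(commonality(y, X[, 1], X[, 2], X[, 3]))
    total <- sum(cm$unique) + sum(cm$shared_pairwise) + cm$shared_all
    expect_lt(abs(total - cm$r2_full), 1e-10)
    # rescaling a predictor changes nothing
    cm2 <- suppressWarnings(commonality(y, 100 * X[, 1], X[, 2], X[, 3]))
    expect_equal(unname(cm$unique), unname(cm2$unique), tolerance = 1e-8)
    expect_equal(cm$shared_all, cm2$shared_all, tolerance = 1e-8)
    # permuting predictors permutes components consistently
    cm3 <- suppressWarnings(commonality(y, X[, 2], X[, 3], X[, 1]))
    expect_equal(unname(cm3$unique), unname(cm$unique)[c(2, 3, 1)],
                 tolerance = 1e-10)
    expect_equal(cm3$shared_all, cm$shared_all, tolerance = 1e-10)
  }
  expect_error(commonality(rnorm(20), rnorm(20), rep(1, 20), rnorm(20)),
               "constant")
  expect_error(commonality(rnorm(5), rnorm(5), rnorm(5), rnorm(5)),
               "more than 10")
})

test_that("correlation-based decomposition agrees with the data route", {
  # closed form: orthogonal predictors, single validity 0.4 -> u_A = 0.16
  cm <- commonality_from_correlations(diag(3), c(0.4, 0, 0))
  expect_equal(unname(cm$unique), c(0.16, 0, 0), tolerance = 1e-12)
  expect_equal(cm$r2_full, 0.16, tolerance = 1e-12)
  expect_lt(max(abs(c(cm$shared_pairwise, cm$shared_all))), 1e-12)

  bad <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3)
  expect_error(commonality_from_correlations(bad, c(0.1, 0.1, 0.1)),
               "positive definite")

  set.seed(22)
  R <- matrix(c(1, 0.4, 0.2, 0.35,
                0.4, 1, 0.3, 0.45,
                0.2, 0.3, 1, 0.25,
                0.35, 0.45, 0.25, 1), 4)
  # data with exactly these sample moments: the two routes must agree
  D <- MASS::mvrnorm(1e5, rep(0, 4), R, empirical = TRUE)
  cm_data <- commonality(D[, 4], D[, 1], D[, 2], D[, 3],
                         labels = c("A", "B", "C"))
  cm_cor <- commonality_from_correlations(R[1:3, 1:3], R[1:3, 4])
  expect_equal(unname(cm_data$unique), unname(cm_cor$unique),
               tolerance = 1e-8)
  expect_equal(unname(cm_data$shared_pairwise),
               unname(cm_cor$shared_pairwise), tolerance = 1e-8)
  expect_equal(cm_data$shared_all, cm_cor$shared_all, tolerance = 1e-8)
})
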