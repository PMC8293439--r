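saturated_spec <- function(vars) {
  n <- length(vars)
  ram_spec(vars, rep(TRUE, n), matrix(0, n, n), matrix(FALSE, n, n),
           diag(n), matrix(TRUE, n, n), "saturated")
}

test_that("a saturated model reproduces the sample matrix exactly", {
  set.seed(14)
  X <- matrix(rnorm(400), 100, 4)
  colnames(X) <- paste0("x", 1:4)
  S <- cov(X)
  fit <- fit_ml(saturated_spec(colnames(X)), S, 100)
  expect_equal(fit$fml, 0)
  expect_equal(fit$chisq, 0)
  expect_equal(fit$df, 0)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$Sigma_hat - S)), 1e-6)
  expect_true(is.na(fit$indices$rmsea))          # undefined at df = 0
  expect_equal(fit$indices$srmr, 0, tolerance = 1e-6)
})

test_that("input validation rejects unusable covariance matrices", {
  spec <- model1_spec()
  S <- diag(9)
  dimnames(S) <- list(spec$vars[1:9], spec$vars[1:9])
  bad <- S; bad[1, 2] <- 0.5                      # asymmetric
  expect_error(fit_ml(spec, bad, 100), "symmetric")
  npd <- matrix(0.99, 9, 9); diag(npd) <- c(rep(1, 8), 0.1)
  dimnames(npd) <- dimnames(S)
  expect_error(fit_ml(spec, npd, 100), "positive definite")
  expect_error(fit_ml(spec, S, 5), "exceed")
  expect_error(fit_ml(spec, S[1:8, 1:8], 100), "lacks|dimension")
})

test_that("a one-factor model recovers its generating loadings", {
  lam <- rep(0.8, 4)
  Sigma <- one_factor_cov(lam)
  vars <- paste0("x", 1:4)
  dimnames(Sigma) <- list(vars, vars)
  set.seed(15)
  n <- 5000
  f <- rnorm(n)
  X <- sapply(1:4, function(j) 0.8 * f + rnorm(n, 0, sqrt(1 - 0.64)))
  colnames(X) <- vars
  m <- new_cfa_1f <- local({
    m <- potsim:::new_ram(vars, "f", "cfa1")
    m <- potsim:::add_factor(m, "f", vars)
    m <- potsim:::add_variance(m, vars)
    potsim:::finish_ram(m)
  })
  fit <- fit_ml(m, cov(X), n)
  expect_true(fit$converged)
  std <- standardized_solution(fit)
  est <- std$std[std$matrix == "A"]
  # 3-SE tolerance for a standardized loading of 0.8 at n = 5000 is ~0.03
  expect_true(all(abs(est - 0.8) < 0.03))
  # and the population matrix is recovered exactly at the population level
  fit_pop <- fit_ml(m, Sigma, 5000)
  std_pop <- standardized_solution(fit_pop)
  expect_equal(std_pop$std[std_pop$matrix == "A"], lam, tolerance = 1e-6)
  expect_equal(fit_pop$chisq, 0, tolerance = 1e-6)
})

test_that("standardized solutions are invariant to the identification rule", {
  set.seed(16)
  vars <- paste0("x", 1:4)
  n <- 800
  f <- rnorm(n)
  X <- sapply(c(0.9, 0.7, 0.6, 0.8),
              function(l) l * f + rnorm(n, 0, sqrt(1 - l^2)))
  colnames(X) <- vars
  S <- cov(X)
  marker <- local({
    m <- potsim:::new_ram(vars, "f", "marker")
    m <- potsim:::add_factor(m, "f", vars)                 # loading 1 fixed
    m <- potsim:::add_variance(m, vars)
    potsim:::finish_ram(m)
  })
  varid <- local({
    m <- potsim:::new_ram(vars, "f", "varid")
    m <- potsim:::add_factor(m, "f", vars, marker = FALSE) # all free
    m$S_free["f", "f"] <- FALSE
    m$S["f", "f"] <- 1                                     # unit variance
    m <- potsim:::add_variance(m, vars)
    potsim:::finish_ram(m)
  })
  f1 <- fit_ml(marker, S, n)
  f2 <- fit_ml(varid, S, n)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-6)
  s1 <- standardized_solution(f1)
  s2 <- standardized_solution(f2)
  l1 <- s1$std[s1$matrix == "A"]
  l2 <- s2$std[s2$matrix == "A"]
  expect_equal(abs(l1), abs(l2), tolerance = 1e-6)
})

test_that("equal correlations give the closed-form sqrt(r) loadings", {
  r <- 0.49
  S <- matrix(r, 3, 3); diag(S) <- 1
  dimnames(S) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- local({
    m <- potsim:::new_ram(c("a", "b", "c"), "f", "equicor")
    m <- potsim:::add_factor(m, "f", c("a", "b", "c"))
    m <- potsim:::add_variance(m, c("a", "b", "c"))
    potsim:::finish_ram(m)
  })
  fit <- fit_ml(m, S, 500)
  std <- standardized_solution(fit)
  expect_equal(std$std[std$matrix == "A"], rep(sqrt(r), 3),
               tolerance = 1e-6)
  expect_equal(fit$fml, 0, tolerance = 1e-10)    # df = 0: exact fit
})

test_that("fit indices clamp and follow their closed forms", {
  fake <- structure(list(chisq = 20, df = 24, N = 1000,
                         S = diag(3), Sigma_hat = diag(3)),
                    class = "potsem_fit")
  fake$S <- matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3)
  fake$Sigma_hat <- fake$S
  idx <- fit_indices(fake)
  expect_equal(idx$rmsea, 0)                     # chisq <= df
  expect_equal(idx$cfi, 1)
  expect_equal(idx$srmr, 0)
  fake2 <- fake
  fake2$chisq <- 26.47
  idx2 <- fit_indices(fake2)
  expect_equal(idx2$rmsea, sqrt(2.47 / (24 * 999)), tolerance = 1e-10)
  expect_equal(round(idx2$rmsea, 4), 0.0101)
  fake3 <- fake
  fake3$chisq <- 144.59; fake3$df <- 51
  expect_equal(round(fit_indices(fake3)$rmsea, 4), 0.0429)
})

test_that("RMSEA confidence bounds invert the noncentral chi-square", {
  expect_equal(rmsea_ci(24, 24, 1000)[1], 0)     # central case
  ci1 <- rmsea_ci(26.47, 24, 1000)
  expect_equal(round(ci1, 2), c(0.00, 0.03))
  ci2 <- rmsea_ci(144.59, 51, 1000)
  expect_equal(round(ci2, 2), c(0.03, 0.05))
  # bounds bracket the point estimate
  point <- sqrt(max(144.59 - 51, 0) / (51 * 999))
  expect_true(ci2[1] <= point && point <= ci2[2])
  # interval consistency: CDF at the solved noncentrality hits 5% / 95%
  lam_hi <- ci2[2]^2 * 51 * 999
  expect_equal(pchisq(144.59, 51, ncp = lam_hi), 0.05, tolerance = 1e-6)
})

test_that("regression factor scores track the latent variable", {
  set.seed(17)
  vars <- paste0("x", 1:4)
  n <- 2000
  f <- rnorm(n)
  X <- sapply(rep(0.8, 4), function(l) l * f + rnorm(n, 0, 0.6))
  colnames(X) <- vars
  m <- local({
    m <- potsim:::new_ram(vars, "f", "cfa1")
    m <- potsim:::add_factor(m, "f", vars)
    m <- potsim:::add_variance(m, vars)
    potsim:::finish_ram(m)
  })
  fit <- fit_ml(m, cov(X), n)
  sc <- factor_scores(fit, X, latent = "f")
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  expect_gt(cor(sc, f), 0.9)
  expect_error(factor_scores(fit, X, latent = "nope"), "no latent")
})
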