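test_that("an iteration is fully reproducible from its seed", {
  cfg <- tiny_config()
  it1 <- suppressWarnings(run_iteration(cfg, seed = 301))
  it2 <- suppressWarnings(run_iteration(cfg, seed = 301))
  expect_identical(it1$scores, it2$scores)
  expect_equal(it1$fit1$chisq, it2$fit1$chisq)
  expect_equal(it1$fit2$estimates, it2$fit2$estimates)
  expect_equal(it1$commonality$r2_full, it2$commonality$r2_full)
  it3 <- suppressWarnings(run_iteration(cfg, seed = 302))
  expect_false(identical(it1$scores, it3$scores))
  # model dfs at full structure
  expect_equal(it1$fit1$df, 24)
  expect_equal(it1$fit2$df, 51)
})

test_that("a degenerate all-processes-sampled configuration still runs", {
  cfg <- sim_config(n_subjects = 120, n_items_per_test = 10,
                    p_fluid = c(1, 1), p_verbal = c(1, 1),
                    p_spatial = c(1, 1), p_ef = c(1, 1))
  sim <- simulate_scores(cfg, 5)
  expect_equal(dim(sim$scores), c(120, 12))
  expect_true(all(is.finite(sim$scores)))
})

test_that("summaries aggregate iterations and degrade gracefully", {
  cfg <- tiny_config()
  its <- suppressWarnings(list(run_iteration(cfg, 401, index = 1),
                               run_iteration(cfg, 402, index = 2)))
  s <- summarize_iterations(its)
  expect_equal(s$n_converged + s$n_failed, 2)
  # recomputation oracle: means equal hand-aggregation of the raw results
  expect_equal(s$fit_model1$mean[["chisq"]],
               mean(c(its[[1]]$fit1$chisq, its[[2]]$fit1$chisq)))
  expect_equal(unname(s$ef_paths_mean),
               unname((its[[1]]$ef_paths + its[[2]]$ef_paths) / 2))
  expect_equal(s$mean_combined_r2,
               mean(c(sum(its[[1]]$ef_paths^2), sum(its[[2]]$ef_paths^2))))
  expect_equal(mean(c(0.38, 0.40)), 0.39)
  # single iteration: zero SDs
  s1 <- summarize_iterations(its[1])
  expect_true(all(s1$fit_model1$sd == 0))
  expect_equal(s1$sd_ef_path, sd(its[[1]]$ef_paths))
  # averaged commonality equals the mean of the per-iteration tables
  s2 <- summarize_iterations(its, avg_commonality = TRUE)
  tab <- (commonality_table(its[[1]]$commonality)$value +
            commonality_table(its[[2]]$commonality)$value) / 2
  expect_equal(s2$commonality_avg$value, tab)
})

test_that("a small study run is deterministic end to end and exports cleanly", {
  cfg <- tiny_config(seed = 77)
  s1 <- suppressWarnings(run_study1(cfg, n_iterations = 2))
  s2 <- suppressWarnings(run_study1(cfg, n_iterations = 2))
  expect_equal(s1$fit_model2$mean, s2$fit_model2$mean)
  expect_equal(s1$ef_paths_mean, s2$ef_paths_mean)
  dir <- tempfile()
  write_summary(s1, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_iterations, 2)
  expect_equal(js$mean_combined_r2, s1$mean_combined_r2, tolerance = 1e-12)
  ld <- read.csv(file.path(dir, "loadings.csv"))
  expect_equal(nrow(ld), 12)
})

test_that("correlation-matrix fits recover a known EF structure", {
  ef_load <- list(c(0.8, 0.7, 0.75), c(0.7, 0.65, 0.6), c(0.75, 0.7, 0.65))
  beta <- c(0.6, 0.15, 0.1)
  Sigma <- ef_population_cov(
    ef_loadings = ef_load, g_loadings = c(0.85, 0.8, 0.75),
    beta = beta, psi = 1 - sum(beta^2),
    resid_ind = 1 - unlist(lapply(ef_load, function(l) l^2)),
    resid_g = 1 - c(0.85, 0.8, 0.75)^2 * 1)
  vars <- c(paste0("U", 1:3), paste0("I", 1:3), paste0("S", 1:3),
            paste0("G", 1:3))
  dimnames(Sigma) <- list(vars, vars)
  expect_equal(diag(Sigma), rep(1, 12), ignore_attr = TRUE)  # correlation metric
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(var = vars, Sigma, check.names = FALSE), csv,
            row.names = FALSE)
  facs <- list(updating = paste0("U", 1:3), inhibition = paste0("I", 1:3),
               shifting = paste0("S", 1:3))
  out <- run_study2(csv, n = 500, factors = facs,
                    criterion = paste0("G", 1:3))
  expect_true(out$fit$converged)
  expect_equal(out$fit$df, 51)
  expect_lt(out$fit$chisq, 1e-4)       # population matrix fits exactly
  std <- standardized_solution(out$fit)
  paths <- std$std[std$matrix == "A" & std$to == "g" &
                     std$from %in% names(facs)]
  expect_equal(paths, beta, tolerance = 1e-4)
  # latent commonality of orthogonal factors: unique = beta^2
  expect_equal(unname(out$commonality$unique), beta^2, tolerance = 1e-6)
  expect_lt(max(abs(c(out$commonality$shared_pairwise,
                      out$commonality$shared_all))), 1e-6)
})

test_that("an identity correlation matrix yields a null structure", {
  vars <- c(paste0("U", 1:3), paste0("I", 1:3), paste0("S", 1:3),
            paste0("G", 1:3))
  I12 <- diag(12)
  dimnames(I12) <- list(vars, vars)
  facs <- list(updating = paste0("U", 1:3), inhibition = paste0("I", 1:3),
               shifting = paste0("S", 1:3))
  out <- suppressWarnings(run_study2(I12, 500, facs, paste0("G", 1:3)))
  # with nothing to explain, the model collapses to independence: exact fit
  expect_lt(out$fit$chisq, 1e-4)
  expect_lt(max(abs(out$fit$Sigma_hat - I12)), 1e-4)
})

test_that("correlation matrix input is validated", {
  csv <- tempfile(fileext = ".csv")
  m <- matrix(c(1, 0.5, 0.4, 1), 2)      # asymmetric
  write.csv(data.frame(var = c("a", "b"), m), csv, row.names = FALSE)
  expect_error(read_cor_matrix(csv), "symmetric")
  facs3 <- list(u = "U1", i = "I1", s = "S1")
  npd <- matrix(0.99, 4, 4); diag(npd) <- c(1, 1, 1, 0.5)
  dimnames(npd) <- list(c("U1", "I1", "S1", "G"), c("U1", "I1", "S1", "G"))
  expect_error(run_study2(npd, 100, facs3, "G"), "positive definite")
})

test_that("a fixed sampling design can be shared across iterations", {
  cfg <- tiny_config(n_subjects = 250, n_items = 20, seed = 55)
  cfg$redraw_design <- FALSE
  s1 <- suppressWarnings(run_study1(cfg, n_iterations = 2,
                                    keep_iterations = TRUE))
  s2 <- suppressWarnings(run_study1(cfg, n_iterations = 2))
  expect_equal(s1$fit_model1$mean, s2$fit_model1$mean)
  its <- attr(s1, "iterations")
  # scores still differ across iterations (abilities/responses redrawn)
  expect_false(identical(its[[1]]$scores, its[[2]]$scores))
})
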