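# Monte-Carlo replication of the simulation study and correlation-matrix
# refits of the executive-function structural model.

std_lookup <- function(std, labels) {
  out <- std$std[match(labels, std$label)]
  names(out) <- labels
  out
}

m1_loading_labels <- function() {
  c(paste0("fluid->", c("Gf1", "Gf2", "Gf3")),
    paste0("verbal->", c("Vb1", "Vb2", "Vb3")),
    paste0("spatial->", c("Sp1", "Sp2", "Sp3")),
    paste0("g->", c("fluid", "verbal", "spatial")))
}

ef_path_labels <- function() paste0(c("Inh", "Upd", "Shf"), "->g")

#' Run one complete simulation iteration
#'
#' Generates abilities, the sampling design, item parameters and responses
#' from the iteration's seed; aggregates test scores; fits the higher-order
#' CFA (Model 1) and its extension with executive function predictors
#' (Model 2) to the score covariance matrix; and decomposes the variance of
#' the g factor scores over the three executive function task scores.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this iteration, from which the four
#'   component streams (abilities, design, difficulties, responses) are
#'   derived.
#' @param index iteration index carried through to the result.
#' @param design optional fixed sampling design passed to
#'   [simulate_scores()].
#' @return A list of class `pot_iteration`: `scores`, `fit1`, `fit2`,
#'   `commonality`, `seed`, `index`, and the standardized loading / path
#'   vectors used by [summarize_iterations()].
#' @export
run_iteration <- function(config, seed, index = 1L, design = NULL) {
  sim <- simulate_scores(config, seed, design = design)
  scores <- sim$scores
  S <- stats::cov(scores)
  fit1 <- fit_ml(model1_spec(), S, config$n_subjects)
  fit2 <- fit_ml(model2_spec(), S, config$n_subjects)
  std1 <- standardized_solution(fit1)
  std2 <- standardized_solution(fit2)
  g_scores <- factor_scores(fit1, scores[, 1:9], latent = "g")
  cm <- commonality(g_scores, scores[, "Inh"], scores[, "Upd"],
                    scores[, "Shf"], labels = c("Inh", "Upd", "Shf"))
  structure(list(
    index = index, seed = seed, scores = scores,
    fit1 = fit1, fit2 = fit2, commonality = cm,
    loadings1 = std_lookup(std1, m1_loading_labels()),
    loadings2 = std_lookup(std2, m1_loading_labels()),
    ef_paths = std_lookup(std2, ef_path_labels())),
    class = "pot_iteration")
}

fit_stats_row <- function(fit) {
  c(chisq = fit$chisq, p = fit$p.value, cfi = fit$indices$cfi,
    rmsea = fit$indices$rmsea, rmsea_lo = fit$indices$rmsea_ci[1],
    rmsea_hi = fit$indices$rmsea_ci[2], srmr = fit$indices$srmr)
}

#' Summarize a set of simulation iterations
#'
#' Averages standardized loadings, executive-function path coefficients and
#' fit statistics over converged iterations (non-converged iterations are
#' excluded and counted; the summary is marked unreliable if more than 5%
#' fail). The structural R-squared of g on the three orthogonal predictors
#' is the per-iteration sum of squared standardized paths. The commonality
#' decomposition reported is the one from the first iteration, with the
#' across-iteration average available via `avg_commonality = TRUE`.
#'
#' @param results list of [run_iteration()] results.
#' @param avg_commonality also average the commonality components across
#'   iterations.
#' @return A list of class `pot_study_summary`.
#' @export
summarize_iterations <- function(results, avg_commonality = FALSE) {
  conv <- vapply(results, function(r) r$fit1$converged && r$fit2$converged,
                 TRUE)
  n_fail <- sum(!conv)
  used <- results[conv]
  if (length(used) == 0) stop("no converged iterations", call. = FALSE)
  mstats <- function(extract) {
    m <- do.call(rbind, lapply(used, extract))
    sds <- if (nrow(m) > 1) apply(m, 2, stats::sd)
           else stats::setNames(rep(0, ncol(m)), colnames(m))
    list(mean = colMeans(m), sd = sds)
  }
  loadings1 <- mstats(function(r) r$loadings1)
  loadings2 <- mstats(function(r) r$loadings2)
  paths <- do.call(rbind, lapply(used, function(r) r$ef_paths))
  fit1 <- mstats(function(r) fit_stats_row(r$fit1))
  fit2 <- mstats(function(r) fit_stats_row(r$fit2))
  r2_iter <- rowSums(paths^2)
  cm1 <- used[[1]]$commonality
  cm_avg <- NULL
  if (avg_commonality) {
    tabs <- lapply(used, function(r) commonality_table(r$commonality)$value)
    cm_avg <- commonality_table(cm1)
    cm_avg$value <- rowMeans(do.call(cbind, tabs))
  }
  structure(list(
    n_iterations = length(results), n_converged = length(used),
    n_failed = n_fail, unreliable = n_fail > 0.05 * length(results),
    loadings_model1 = loadings1, loadings_model2 = loadings2,
    fit_model1 = fit1, fit_model2 = fit2,
    ef_paths_mean = colMeans(paths), ef_paths_sd = apply(paths, 2, stats::sd),
    mean_ef_path = mean(paths), sd_ef_path = stats::sd(paths),
    mean_path_r2 = mean(paths^2), mean_combined_r2 = mean(r2_iter),
    commonality = cm1, commonality_avg = cm_avg),
    class = "pot_study_summary")
}

#' Run the full Monte-Carlo simulation study
#'
#' Repeats [run_iteration()] `n_iterations` times with per-iteration seeds
#' derived deterministically from the configuration's master seed, then
#' aggregates with [summarize_iterations()].
#'
#' @param config a [sim_config()].
#' @param n_iterations override `config$n_iterations`.
#' @param progress print a one-line log per iteration to stderr.
#' @param avg_commonality passed to [summarize_iterations()].
#' @param keep_iterations attach the full list of iteration results as
#'   attribute `iterations`.
#' @return A `pot_study_summary`.
#' @export
run_study1 <- function(config = sim_config(),
                       n_iterations = config$n_iterations,
                       progress = FALSE, avg_commonality = FALSE,
                       keep_iterations = FALSE) {
  set.seed(config$master_seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  shared_design <- if (config$redraw_design) NULL
                   else build_design(default_blueprints(config))
  results <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    results[[i]] <- run_iteration(config, iter_seeds[i], index = i,
                                  design = shared_design)
    if (progress)
      message(sprintf(
        "iter %3d seed %10d chisq1 %7.2f chisq2 %7.2f conv %s/%s",
        i, iter_seeds[i], results[[i]]$fit1$chisq, results[[i]]$fit2$chisq,
        results[[i]]$fit1$converged, results[[i]]$fit2$converged))
  }
  out <- summarize_iterations(results, avg_commonality = avg_commonality)
  if (keep_iterations) attr(out, "iterations") <- results
  out
}

#' @export
print.pot_study_summary <- function(x, ...) {
  cat("Simulation study summary:", x$n_converged, "of", x$n_iterations,
      "iterations converged",
      if (x$unreliable) "[UNRELIABLE: >5% failed]" else "", "\n")
  f <- function(s) sprintf(
    "chisq = %.2f, p = %.2f, CFI = %.3f, RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f",
    s$mean[["chisq"]], s$mean[["p"]], s$mean[["cfi"]], s$mean[["rmsea"]],
    s$mean[["rmsea_lo"]], s$mean[["rmsea_hi"]], s$mean[["srmr"]])
  cat("  Model 1 mean fit:", f(x$fit_model1), "\n")
  cat("  Model 2 mean fit:", f(x$fit_model2), "\n")
  cat(sprintf(
    "  EF->g standardized paths: M = %.3f (SD = %.3f); per-path R2 = %.3f; combined R2 = %.3f\n",
    x$mean_ef_path, x$sd_ef_path, x$mean_path_r2, x$mean_combined_r2))
  cat("  Commonality (first iteration):\n")
  print(x$commonality)
  invisible(x)
}

#' Export a study summary as JSON and CSV
#'
#' Writes `summary.json` (all aggregate quantities) plus
#' `loadings.csv` and `fit_stats.csv` parameter tables into `dir`.
#'
#' @param summary a `pot_study_summary`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    n_iterations = summary$n_iterations, n_converged = summary$n_converged,
    n_failed = summary$n_failed, unreliable = summary$unreliable,
    fit_model1 = summary$fit_model1, fit_model2 = summary$fit_model2,
    loadings_model1 = summary$loadings_model1,
    loadings_model2 = summary$loadings_model2,
    ef_paths_mean = summary$ef_paths_mean,
    mean_ef_path = summary$mean_ef_path, sd_ef_path = summary$sd_ef_path,
    mean_path_r2 = summary$mean_path_r2,
    mean_combined_r2 = summary$mean_combined_r2,
    commonality = as.list(stats::setNames(
      commonality_table(summary$commonality)$value,
      commonality_table(summary$commonality)$component)))
  jsonlite::write_json(payload, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ld <- data.frame(label = names(summary$loadings_model1$mean),
                   model1_mean = summary$loadings_model1$mean,
                   model1_sd = summary$loadings_model1$sd,
                   model2_mean = summary$loadings_model2$mean,
                   model2_sd = summary$loadings_model2$sd)
  utils::write.csv(ld, file.path(dir, "loadings.csv"), row.names = FALSE)
  fs <- rbind(
    data.frame(model = "model1", stat = names(summary$fit_model1$mean),
               mean = summary$fit_model1$mean, sd = summary$fit_model1$sd),
    data.frame(model = "model2", stat = names(summary$fit_model2$mean),
               mean = summary$fit_model2$mean, sd = summary$fit_model2$sd))
  utils::write.csv(fs, file.path(dir, "fit_stats.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a correlation matrix from CSV
#'
#' Expects a square matrix with a header row and the variable names in the
#' first column.
#'
#' @param path CSV file.
#' @return Named symmetric numeric matrix.
#' @export
read_cor_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != ncol(m))
    stop("correlation matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(unname(m), unname(t(m)), tolerance = 1e-6)))
    stop("correlation matrix is not symmetric", call. = FALSE)
  m
}

#' Fit the executive-function structural model to a correlation matrix
#'
#' Fits [study2_spec()] by maximum likelihood to a user-supplied
#' correlation matrix (treated as the covariance matrix of standardized
#' variables with the supplied sample size) and decomposes the variance of
#' g across the three executive function factors at the latent level: the
#' model-implied latent correlations and validities feed
#' [commonality_from_correlations()].
#'
#' @param matrix a correlation matrix, or the path of a CSV readable by
#'   [read_cor_matrix()].
#' @param n sample size behind the matrix.
#' @param factors,criterion,ef_correlations passed to [study2_spec()].
#' @return A list with elements `fit` (a `potsem_fit`) and `commonality`
#'   (a `pot_commonality`, `NULL` when the model has fewer than three
#'   executive function factors).
#' @export
run_study2 <- function(matrix, n, factors, criterion,
                       ef_correlations = "orthogonal") {
  if (is.character(matrix)) matrix <- read_cor_matrix(matrix)
  ev <- eigen(as.matrix(matrix), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")", call. = FALSE)
  spec <- study2_spec(factors, criterion,
                      ef_correlations = ef_correlations)
  fit <- fit_ml(spec, matrix, n)
  cm <- NULL
  if (length(factors) == 3) {
    gvar <- if (length(criterion) > 1) "g" else criterion
    V <- ram_covariance(spec, unname(fit$estimates))
    sub <- V[c(names(factors), gvar), c(names(factors), gvar)]
    if (all(diag(sub) > 0)) {
      cors <- stats::cov2cor(sub)
      cm <- tryCatch(
        commonality_from_correlations(
          cors[names(factors), names(factors)],
          cors[names(factors), gvar], labels = names(factors)),
        error = function(e) {
          warning("latent commonality unavailable: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
    } else {
      warning("latent commonality unavailable: a latent variance ",
              "estimate is not positive", call. = FALSE)
    }
  }
  list(fit = fit, commonality = cm)
}
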