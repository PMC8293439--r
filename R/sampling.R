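#' Default battery of test blueprints
#'
#' The simulated battery contains twelve tests: three fluid, three verbal and
#' three spatial broad-ability tests, plus one executive function task each
#' for inhibition, updating and shifting. Every test samples processes from
#' two disjoint pools:
#' \itemize{
#'   \item broad tests: the full executive attention block (general pool) and
#'     their own domain block (specific pool);
#'   \item EF tasks: the "common" EA sub-pool (general) and their own EA
#'     sub-pool (specific).
#' }
#' The EA processes drawn on by the EF tasks are the same pool drawn on by
#' the nine broad tests, which is what ties EF performance to the general
#' factor downstream.
#'
#' @param config a [sim_config()].
#' @return A list of class `pot_blueprints`; each element describes one test:
#'   `test`, `class`, `n_items`, `general_idx`, `specific_idx`, `p_general`,
#'   `p_specific`, `b_sd`, `discrimination`.
#' @examples
#' bp <- default_blueprints(sim_config())
#' length(bp)  # 12
#' @export
default_blueprints <- function(config = sim_config()) {
  stopifnot(inherits(config, "pot_config"))
  tax <- config$taxonomy
  ea_all <- pool_index(tax, domain = "ea")
  common <- pool_index(tax, subdomain = "common")
  sp <- config$sampling_probs
  sd_broad <- config$difficulty_sd[["broad"]]
  sd_ef <- config$difficulty_sd[["ef"]]
  bp <- list()
  broad <- list(fluid = "Gf", verbal = "Vb", spatial = "Sp")
  for (dom in names(broad)) {
    for (k in 1:3) {
      bp[[length(bp) + 1L]] <- list(
        test = paste0(broad[[dom]], k), class = dom,
        n_items = config$n_items_per_test,
        general_idx = ea_all,
        specific_idx = pool_index(tax, domain = dom),
        p_general = sp[[dom]][1], p_specific = sp[[dom]][2],
        b_sd = sd_broad, discrimination = config$discrimination)
    }
  }
  ef <- c(Inh = "inhibition", Upd = "updating", Shf = "shifting")
  for (nm in names(ef)) {
    bp[[length(bp) + 1L]] <- list(
      test = nm, class = paste0("ef_", ef[[nm]]),
      n_items = config$n_items_per_test,
      general_idx = common,
      specific_idx = pool_index(tax, subdomain = ef[[nm]]),
      p_general = sp$ef[1], p_specific = sp$ef[2],
      b_sd = sd_ef, discrimination = config$discrimination)
  }
  names(bp) <- vapply(bp, `[[`, "", "test")
  for (b in bp) {
    if (length(intersect(b$general_idx, b$specific_idx)) > 0)
      stop("general and specific pools overlap for test ", b$test,
           call. = FALSE)
  }
  class(bp) <- "pot_blueprints"
  bp
}

#' Draw one binary process-sampling vector
#'
#' Each entry indicates whether the corresponding process in the pool is
#' sampled by (contributes to) an item, drawn independently as Bernoulli(p).
#' An all-zero vector is a legitimate outcome (the item then carries zero
#' aggregate ability on that dimension and is handled by the degenerate rule
#' in [standardize_theta()]); the expected number of sampled processes is
#' exactly `pool_size * p`.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param pool_size number of processes in the pool.
#' @param p Bernoulli sampling probability.
#' @return Integer vector of 0/1 of length `pool_size`.
#' @examples
#' set.seed(1)
#' draw_sampling_vector(50, 0.12)
#' @export
draw_sampling_vector <- function(pool_size, p) {
  if (pool_size < 1) stop("pool_size must be >= 1", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("sampling probability must lie in [0, 1]", call. = FALSE)
  stats::rbinom(pool_size, 1L, p)
}

#' Draw the full sampling design for a battery
#'
#' For every item of every test, draws one binary sampling vector over the
#' test's general pool and one over its specific pool. Vectors are indexed by
#' (test, item) only: all persons share the same sampling pattern for a given
#' item, and the design is typically redrawn fresh in each Monte-Carlo
#' iteration.
#'
#' @param blueprints a [default_blueprints()] list.
#' @param seed optional integer seed.
#' @return A list of class `pot_design`; per test a list with binary matrices
#'   `general` and `specific` (`n_items` rows, pool-size columns) and the
#'   pool column indices.
#' @export
build_design <- function(blueprints, seed = NULL) {
  stopifnot(inherits(blueprints, "pot_blueprints"))
  if (!is.null(seed)) set.seed(seed)
  design <- lapply(blueprints, function(b) {
    ng <- length(b$general_idx)
    ns <- length(b$specific_idx)
    list(
      test = b$test,
      general = matrix(stats::rbinom(b$n_items * ng, 1L, b$p_general),
                       nrow = b$n_items, ncol = ng),
      specific = matrix(stats::rbinom(b$n_items * ns, 1L, b$p_specific),
                        nrow = b$n_items, ncol = ns),
      general_idx = b$general_idx,
      specific_idx = b$specific_idx)
  })
  class(design) <- "pot_design"
  design
}

#' Aggregate sampled process abilities into theta parameters
#'
#' For person p, test t, item i the domain-general aggregate ability is the
#' sum of the person's abilities over the processes the item samples from the
#' general pool, and likewise for the domain-specific aggregate:
#' `theta = <sampling vector, person abilities in pool>`. Computed as one
#' matrix product per test.
#'
#' @param design a [build_design()] result.
#' @param abilities a [generate_abilities()] matrix.
#' @return A list of class `pot_theta` with three-dimensional arrays
#'   `theta_g` and `theta_s` of shape persons x tests x items (test ids on
#'   the second dimension).
#' @export
aggregate_theta <- function(design, abilities) {
  stopifnot(inherits(design, "pot_design"))
  n_items <- nrow(design[[1]]$general)
  n_sub <- nrow(abilities)
  tests <- unname(vapply(design, `[[`, "", "test"))
  tg <- array(0, dim = c(n_sub, length(design), n_items),
              dimnames = list(NULL, tests, NULL))
  ts <- tg
  for (k in seq_along(design)) {
    d <- design[[k]]
    if (max(d$general_idx) > ncol(abilities) ||
        max(d$specific_idx) > ncol(abilities))
      stop("design pools index beyond the ability matrix", call. = FALSE)
    tg[, k, ] <- abilities[, d$general_idx, drop = FALSE] %*% t(d$general)
    ts[, k, ] <- abilities[, d$specific_idx, drop = FALSE] %*% t(d$specific)
  }
  structure(list(theta_g = tg, theta_s = ts, tests = tests),
            class = "pot_theta")
}
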