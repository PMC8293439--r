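#' Define a cognitive process taxonomy
#'
#' The simulated mind consists of a pool of elementary cognitive processes
#' partitioned into domains: three domain-specific blocks (fluid, verbal,
#' spatial) and one domain-general executive attention (EA) block. The EA
#' block is further subdivided into sub-pools for inhibition, updating and
#' shifting processes, a set of unspecified EA processes, and a set of
#' "common" EA processes that every executive function task can draw on.
#'
#' @param fluid,verbal,spatial number of processes in each domain-specific
#'   block (default 50 each).
#' @param ea named integer vector of executive attention sub-block sizes;
#'   must contain the names `inhibition`, `updating`, `shifting`,
#'   `unspecified`, `common` (default 10 each).
#'
#' @return A data frame of class `pot_taxonomy` with one row per process and
#'   columns `process` (unique id), `domain` and `subdomain`. Row order fixes
#'   the column order of ability matrices, so sampling designs can index
#'   processes deterministically.
#' @examples
#' tax <- process_taxonomy()
#' nrow(tax)          # 200
#' table(tax$domain)
#' @export
process_taxonomy <- function(fluid = 50, verbal = 50, spatial = 50,
                             ea = c(inhibition = 10, updating = 10,
                                    shifting = 10, unspecified = 10,
                                    common = 10)) {
  sizes <- c(fluid = fluid, verbal = verbal, spatial = spatial, ea)
  if (any(sizes < 1) || any(sizes != round(sizes)))
    stop("all taxonomy block sizes must be positive integers", call. = FALSE)
  required <- c("inhibition", "updating", "shifting", "unspecified", "common")
  if (!all(required %in% names(ea)))
    stop("`ea` must name sub-blocks: ", paste(required, collapse = ", "),
         call. = FALSE)
  blocks <- rbind(
    data.frame(domain = "fluid", subdomain = "fluid", n = fluid),
    data.frame(domain = "verbal", subdomain = "verbal", n = verbal),
    data.frame(domain = "spatial", subdomain = "spatial", n = spatial),
    data.frame(domain = "ea", subdomain = names(ea), n = unname(ea))
  )
  tax <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    data.frame(
      process = sprintf("%s_%02d", b$subdomain, seq_len(b$n)),
      domain = b$domain, subdomain = b$subdomain,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tax) <- NULL
  if (anyDuplicated(tax$process))
    stop("process labels are not unique", call. = FALSE)
  class(tax) <- c("pot_taxonomy", "data.frame")
  tax
}

#' Column indices of a taxonomy sub-pool
#'
#' @param taxonomy a [process_taxonomy()] data frame.
#' @param domain domain label, or `NULL` to select on `subdomain` only.
#' @param subdomain subdomain label, or `NULL` to select a whole domain.
#' @return Integer vector of process (column) indices.
#' @keywords internal
pool_index <- function(taxonomy, domain = NULL, subdomain = NULL) {
  keep <- rep(TRUE, nrow(taxonomy))
  if (!is.null(domain)) keep <- keep & taxonomy$domain == domain
  if (!is.null(subdomain)) keep <- keep & taxonomy$subdomain == subdomain
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("pool not found in taxonomy: domain=", domain %||% "*",
         " subdomain=", subdomain %||% "*", call. = FALSE)
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Bundles every tunable of the test-battery simulation: sample size, the
#' process taxonomy, items per test, the per-test-class process sampling
#' probabilities, difficulty-distribution scales, the common discrimination
#' parameter, and Monte-Carlo controls.
#'
#' Defaults reproduce the study conditions: 1000 subjects, 200 processes,
#' 12 tests of 100 items. Verbal and spatial test items sample executive
#' attention processes with probability 0.12 and own-domain processes with
#' probability 0.28; fluid items reverse the two (0.28 general / 0.12
#' specific); executive function (EF) items sample their task-specific EA
#' sub-pool with probability 0.28 and the common EA sub-pool with 0.12.
#' Item difficulties are centered at zero with standard deviation 1 for the
#' nine broad-ability tests and 0.05 for the three EF tasks (EF task
#' performance is comparatively stable); all discriminations are 1.
#'
#' @param n_subjects number of simulated persons.
#' @param taxonomy a [process_taxonomy()].
#' @param n_items_per_test items per test.
#' @param p_fluid,p_verbal,p_spatial,p_ef length-2 numeric vectors
#'   `c(p_general, p_specific)` of Bernoulli sampling probabilities.
#' @param difficulty_sd named numeric vector with elements `broad` and `ef`:
#'   standard deviations of the item difficulty distributions.
#' @param discrimination common logistic slope for all items.
#' @param n_iterations Monte-Carlo iterations for [run_study1()].
#' @param master_seed integer seed from which all per-iteration random
#'   streams are derived.
#' @param redraw_design if `TRUE` (default) sampling vectors are redrawn in
#'   every Monte-Carlo iteration along with everything else.
#'
#' @return A list of class `pot_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 200, n_items_per_test = 20)
#' @export
sim_config <- function(n_subjects = 1000,
                       taxonomy = process_taxonomy(),
                       n_items_per_test = 100,
                       p_fluid = c(0.28, 0.12),
                       p_verbal = c(0.12, 0.28),
                       p_spatial = c(0.12, 0.28),
                       p_ef = c(0.12, 0.28),
                       difficulty_sd = c(broad = 1, ef = 0.05),
                       discrimination = 1,
                       n_iterations = 200,
                       master_seed = 1L,
                       redraw_design = TRUE) {
  probs <- list(fluid = p_fluid, verbal = p_verbal, spatial = p_spatial,
                ef = p_ef)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (length(p) != 2 || any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("sampling probabilities for ", nm,
           " must be two values in [0, 1]", call. = FALSE)
  }
  counts <- c(n_subjects = n_subjects, n_items_per_test = n_items_per_test,
              n_iterations = n_iterations)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers", call. = FALSE)
  if (!all(c("broad", "ef") %in% names(difficulty_sd)) ||
      any(difficulty_sd[c("broad", "ef")] <= 0))
    stop("difficulty_sd must have positive elements 'broad' and 'ef'",
         call. = FALSE)
  if (discrimination <= 0)
    stop("discrimination must be positive", call. = FALSE)
  stopifnot(inherits(taxonomy, "pot_taxonomy"))
  structure(list(
    n_subjects = as.integer(n_subjects),
    taxonomy = taxonomy,
    n_items_per_test = as.integer(n_items_per_test),
    sampling_probs = probs,
    difficulty_sd = difficulty_sd[c("broad", "ef")],
    discrimination = discrimination,
    n_iterations = as.integer(n_iterations),
    master_seed = as.integer(master_seed),
    redraw_design = isTRUE(redraw_design)
  ), class = "pot_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Any field of [sim_config()] may appear in the file; missing fields take
#' their defaults. Taxonomy block sizes may be given under a `taxonomy` entry
#' with keys `fluid`, `verbal`, `spatial` and an `ea` mapping.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pot_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$taxonomy)) {
    tx <- raw$taxonomy
    args$taxonomy <- process_taxonomy(
      fluid = tx$fluid %||% 50, verbal = tx$verbal %||% 50,
      spatial = tx$spatial %||% 50,
      ea = if (is.null(tx$ea)) c(inhibition = 10, updating = 10,
                                 shifting = 10, unspecified = 10,
                                 common = 10) else unlist(tx$ea)
    )
  }
  scalar <- c("n_subjects", "n_items_per_test", "discrimination",
              "n_iterations", "master_seed", "redraw_design")
  for (nm in scalar) if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  for (nm in c("p_fluid", "p_verbal", "p_spatial", "p_ef"))
    if (!is.null(raw[[nm]])) args[[nm]] <- as.numeric(unlist(raw[[nm]]))
  if (!is.null(raw$difficulty_sd))
    args$difficulty_sd <- unlist(raw$difficulty_sd)
  do.call(sim_config, args)
}

#' @export
print.pot_config <- function(x, ...) {
  cat("POT simulation configuration\n")
  cat("  subjects:", x$n_subjects, " processes:", nrow(x$taxonomy),
      " items/test:", x$n_items_per_test, "\n")
  cat("  sampling p (general/specific):",
      paste(sprintf("%s=%.2f/%.2f", names(x$sampling_probs),
                    vapply(x$sampling_probs, `[`, 0, 1),
                    vapply(x$sampling_probs, `[`, 0, 2)), collapse = " "),
      "\n")
  cat("  difficulty SD broad:", x$difficulty_sd[["broad"]],
      " ef:", x$difficulty_sd[["ef"]],
      " discrimination:", x$discrimination, "\n")
  cat("  iterations:", x$n_iterations, " master seed:", x$master_seed, "\n")
  invisible(x)
}

#' Generate the orthogonal person-by-process ability matrix
#'
#' Each person receives an ability value on every process in the taxonomy,
#' drawn from a standardized multivariate normal distribution with identity
#' covariance. Because the covariance is the identity, the draw is realized
#' as independent univariate standard normals; processes are orthogonal in
#' expectation and no correlation structure is imposed.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; if supplied the global RNG is seeded, making
#'   the matrix reproducible.
#' @return A numeric matrix (`n_subjects` rows, one column per process,
#'   column names = process ids) with the taxonomy attached as attribute
#'   `taxonomy`.
#' @examples
#' cfg <- sim_config(n_subjects = 100)
#' ab <- generate_abilities(cfg, seed = 1)
#' dim(ab)  # 100 x 200
#' @export
generate_abilities <- function(config, seed = NULL) {
  stopifnot(inherits(config, "pot_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(config$taxonomy)
  m <- matrix(stats::rnorm(config$n_subjects * p),
              nrow = config$n_subjects, ncol = p,
              dimnames = list(NULL, config$taxonomy$process))
  attr(m, "taxonomy") <- config$taxonomy
  m
}

# Deterministic sub-seed derivation: one row per iteration, one named column
# per random component, all in [1, 2^31 - 2].
derive_seeds <- function(master_seed, n_iterations) {
  set.seed(master_seed)
  streams <- c("abilities", "design", "difficulties", "responses")
  m <- matrix(sample.int(.Machine$integer.max - 1L,
                         n_iterations * length(streams)),
              nrow = n_iterations,
              dimnames = list(NULL, streams))
  m
}
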