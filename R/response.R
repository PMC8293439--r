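#' Standardize aggregate theta parameters
#'
#' Each (test, item) slice of the theta arrays is z-scored across persons:
#' subtract the cross-person mean and divide by the cross-person standard
#' deviation (sample convention, n - 1). Standardization puts the aggregate
#' ability on the same scale as the item difficulties, which are drawn from
#' zero-centered normal distributions. If an item's theta is constant across
#' persons — which happens whenever its sampling vector is all-zero — the SD
#' is zero and the z-score is defined as 0 for everyone.
#'
#' @param theta a [aggregate_theta()] result.
#' @return A `pot_theta` list with both arrays standardized.
#' @export
standardize_theta <- function(theta) {
  stopifnot(inherits(theta, "pot_theta"))
  zscore <- function(a) {
    d <- dim(a)
    m <- matrix(a, nrow = d[1])           # persons x (tests*items)
    mu <- colMeans(m)
    sdv <- sqrt(colSums(sweep(m, 2, mu)^2) / (d[1] - 1))
    z <- sweep(m, 2, mu)
    nz <- sdv > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
    z[, !nz] <- 0
    array(z, dim = d, dimnames = dimnames(a))
  }
  theta$theta_g <- zscore(theta$theta_g)
  theta$theta_s <- zscore(theta$theta_s)
  theta
}

#' Draw item difficulty parameters
#'
#' Difficulties for the general (`b_g`) and specific (`b_s`) dimension of
#' every item are independent normal draws centered at 0, with standard
#' deviation taken from the test's blueprint: 1 for broad-ability tests and
#' 0.05 for executive function tasks, whose trial-to-trial difficulty is
#' comparatively homogeneous. Discriminations are the configured constant.
#'
#' @param blueprints a [default_blueprints()] list.
#' @param seed optional integer seed.
#' @return A list of class `pot_itembank`; per test, numeric vectors `b_g`
#'   and `b_s` of length `n_items` plus scalars `a_g`, `a_s`.
#' @export
draw_item_difficulties <- function(blueprints, seed = NULL) {
  stopifnot(inherits(blueprints, "pot_blueprints"))
  if (!is.null(seed)) set.seed(seed)
  bank <- lapply(blueprints, function(b) {
    list(test = b$test,
         b_g = stats::rnorm(b$n_items, 0, b$b_sd),
         b_s = stats::rnorm(b$n_items, 0, b$b_sd),
         a_g = b$discrimination, a_s = b$discrimination)
  })
  class(bank) <- "pot_itembank"
  bank
}

#' Non-compensatory multidimensional response probability
#'
#' The probability of a correct response is the product over dimensions of
#' two-parameter logistic terms, `prod(plogis(a * (z - b)))`. The model is
#' compensatory within a dimension (abilities already entered `z` as a sum)
#' but non-compensatory across dimensions: every dimension must be passed,
#' and a deficit on one cannot be offset by strength on another. With two
#' dimensions and unit discrimination this is the item response function
#' used to generate all simulated responses.
#'
#' @param z numeric vector of standardized aggregate abilities, one per
#'   dimension.
#' @param b numeric vector of difficulties, one per dimension (recycled).
#' @param a positive discriminations (recycled).
#' @return A single probability in (0, 1).
#' @examples
#' pot_probability(c(0, 0), c(0, 0))        # 0.25
#' pot_probability(c(1, 1), c(0, 0))        # plogis(1)^2
#' @export
pot_probability <- function(z, b, a = 1) {
  if (length(z) < 1) stop("at least one dimension is required", call. = FALSE)
  if (any(a <= 0)) stop("discriminations must be positive", call. = FALSE)
  prod(stats::plogis(a * (z - b)))
}

# Vectorized two-dimensional response surface for a whole battery:
# persons x tests x items probability array from standardized thetas and an
# item bank.
response_probabilities <- function(ztheta, bank) {
  stopifnot(inherits(ztheta, "pot_theta"), inherits(bank, "pot_itembank"))
  dims <- dim(ztheta$theta_g)
  P <- array(0, dim = dims, dimnames = dimnames(ztheta$theta_g))
  for (k in seq_along(bank)) {
    bg <- matrix(bank[[k]]$b_g, nrow = dims[1], ncol = dims[3], byrow = TRUE)
    bs <- matrix(bank[[k]]$b_s, nrow = dims[1], ncol = dims[3], byrow = TRUE)
    P[, k, ] <- stats::plogis(bank[[k]]$a_g * (ztheta$theta_g[, k, ] - bg)) *
      stats::plogis(bank[[k]]$a_s * (ztheta$theta_s[, k, ] - bs))
  }
  P
}

#' Draw binary item responses
#'
#' Each cell of the probability array is realized as an independent
#' Bernoulli trial.
#'
#' @param P numeric array of probabilities in \[0, 1\].
#' @param seed optional integer seed.
#' @return Integer 0/1 array of the same shape.
#' @export
draw_responses <- function(P, seed = NULL) {
  if (any(P < 0 | P > 1, na.rm = TRUE) || anyNA(P))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  U <- array(stats::rbinom(length(P), 1L, P), dim = dim(P),
             dimnames = dimnames(P))
  U
}

#' Aggregate binary responses into test scores
#'
#' Sums correct responses over items, giving one integer score per person
#' per test (0 to the number of items).
#'
#' @param responses persons x tests x items binary array.
#' @return Integer matrix persons x tests with test ids as column names.
#' @export
aggregate_scores <- function(responses) {
  d <- dim(responses)
  scores <- sapply(seq_len(d[2]), function(t)
    rowSums(responses[, t, , drop = FALSE]))
  colnames(scores) <- dimnames(responses)[[2]]
  storage.mode(scores) <- "integer"
  scores
}

#' Write a score matrix to CSV
#'
#' @param scores persons x tests matrix from [aggregate_scores()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  df <- data.frame(subject = seq_len(nrow(scores)), scores,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Simulate one complete score matrix
#'
#' Runs the four generative steps — abilities, sampling design, item
#' parameters, responses — and returns the aggregated person x test score
#' matrix together with the intermediate objects.
#'
#' @param config a [sim_config()].
#' @param seeds named integer vector with elements `abilities`, `design`,
#'   `difficulties`, `responses` (one RNG stream per component), or a single
#'   integer used to derive all four.
#' @param design optional pre-built [build_design()] result, reused instead
#'   of drawing a fresh one (for studies holding the sampling design fixed
#'   across iterations).
#' @return A list with `scores`, `abilities`, `design`, `bank`, `ztheta`.
#' @export
simulate_scores <- function(config, seeds, design = NULL) {
  if (length(seeds) == 1L) seeds <- derive_seeds(seeds, 1L)[1L, ]
  bp <- default_blueprints(config)
  abilities <- generate_abilities(config, seed = seeds[["abilities"]])
  if (is.null(design))
    design <- build_design(bp, seed = seeds[["design"]])
  bank <- draw_item_difficulties(bp, seed = seeds[["difficulties"]])
  ztheta <- standardize_theta(aggregate_theta(design, abilities))
  P <- response_probabilities(ztheta, bank)
  U <- draw_responses(P, seed = seeds[["responses"]])
  list(scores = aggregate_scores(U), abilities = abilities, design = design,
       bank = bank, ztheta = ztheta)
}
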