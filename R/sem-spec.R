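#' RAM-parameterized structural equation model specification
#'
#' Models are held in reticular-action-model form: a directed-path matrix
#' `A` (entry `A[i, j]` is the path from variable `j` to variable `i`,
#' loadings and regressions alike) and a symmetric matrix `S` of variances
#' and covariances of exogenous terms and residuals. Logical companions
#' `A_free` / `S_free` mark free parameters; numeric entries of `A` / `S`
#' hold fixed values (markers fixed at 1, forbidden paths at 0). The model-
#' implied covariance of the observed variables is
#' `[(I - A)^-1 S (I - A)^-T]` restricted to observed rows/columns.
#'
#' @param vars character vector of all variable names, observed and latent.
#' @param observed logical vector marking observed variables.
#' @param A,A_free numeric / logical path matrices (`vars` x `vars`).
#' @param S,S_free numeric / logical symmetric (co)variance matrices.
#' @param name optional model label.
#' @return An object of class `potsem_spec`.
#' @export
ram_spec <- function(vars, observed, A, A_free, S, S_free, name = "model") {
  n <- length(vars)
  stopifnot(length(observed) == n,
            all(dim(A) == n), all(dim(A_free) == n),
            all(dim(S) == n), all(dim(S_free) == n))
  if (!isTRUE(all.equal(unname(S), unname(t(S)))) ||
      !all(S_free == t(S_free)))
    stop("S and S_free must be symmetric", call. = FALSE)
  dimnames(A) <- dimnames(A_free) <- dimnames(S) <- dimnames(S_free) <-
    list(vars, vars)
  spec <- structure(list(vars = vars, observed = observed,
                         A = A, A_free = A_free, S = S, S_free = S_free,
                         name = name),
                    class = "potsem_spec")
  spec$pt <- enumerate_params(spec)
  pt <- spec$pt
  loads <- rowSums(abs(spec$A[, , drop = FALSE]) > 0 | spec$A_free)
  covs <- rowSums(abs(spec$S) > 0 | spec$S_free)
  if (any(observed & loads == 0 & covs == 0))
    stop("observed variable appears in no equation: ",
         paste(vars[observed & loads == 0 & covs == 0], collapse = ", "),
         call. = FALSE)
  spec$n_free <- nrow(pt)
  spec
}

# Enumerate free parameters: A entries, then lower triangle of S. Linear
# indices into the n x n matrices are precomputed so filling is vectorized.
enumerate_params <- function(spec) {
  n <- length(spec$vars)
  ai <- which(spec$A_free, arr.ind = TRUE)
  si <- which(spec$S_free & lower.tri(spec$S_free, diag = TRUE),
              arr.ind = TRUE)
  pt <- rbind(
    data.frame(matrix = character(), row = integer(), col = integer(),
               label = character()),
    if (nrow(ai)) data.frame(matrix = "A", row = ai[, 1], col = ai[, 2],
                             label = paste0(spec$vars[ai[, 2]], "->",
                                            spec$vars[ai[, 1]])),
    if (nrow(si)) data.frame(matrix = "S", row = si[, 1], col = si[, 2],
                             label = paste0(spec$vars[si[, 1]], "~~",
                                            spec$vars[si[, 2]]))
  )
  attr(pt, "a_lin") <- (ai[, 2] - 1L) * n + ai[, 1]
  attr(pt, "s_lin") <- (si[, 2] - 1L) * n + si[, 1]
  attr(pt, "s_lin_t") <- (si[, 1] - 1L) * n + si[, 2]
  pt
}

param_table <- function(spec) {
  spec$pt %||% enumerate_params(spec)
}

# Insert a parameter vector into the A and S matrices.
fill_params <- function(spec, params) {
  pt <- param_table(spec)
  if (length(params) != nrow(pt))
    stop("expected ", nrow(pt), " parameters, got ", length(params),
         call. = FALSE)
  A <- spec$A
  S <- spec$S
  na <- sum(pt$matrix == "A")
  if (na) A[attr(pt, "a_lin")] <- params[seq_len(na)]
  if (nrow(pt) > na) {
    sv <- params[(na + 1L):nrow(pt)]
    S[attr(pt, "s_lin")] <- sv
    S[attr(pt, "s_lin_t")] <- sv
  }
  list(A = A, S = S)
}

# Covariance matrix of ALL variables (observed + latent) implied by params.
ram_covariance <- function(spec, params) {
  mats <- fill_params(spec, params)
  n <- length(spec$vars)
  B <- solve(diag(n) - mats$A)
  V <- B %*% mats$S %*% t(B)
  dimnames(V) <- list(spec$vars, spec$vars)
  V
}

#' Model-implied covariance matrix
#'
#' @param spec a [ram_spec()] model.
#' @param params numeric vector of free parameter values, in the order of
#'   the model's parameter table (`A` entries then lower-triangular `S`).
#' @return Symmetric covariance matrix over the observed variables.
#' @export
implied_covariance <- function(spec, params) {
  V <- ram_covariance(spec, params)
  V[spec$observed, spec$observed, drop = FALSE]
}

#' @export
print.potsem_spec <- function(x, ...) {
  p <- sum(x$observed)
  cat("SEM specification '", x$name, "': ", p, " observed, ",
      sum(!x$observed), " latent, ", x$n_free, " free parameters (df = ",
      p * (p + 1) / 2 - x$n_free, ")\n", sep = "")
  invisible(x)
}

# --- incremental builder -----------------------------------------------

new_ram <- function(observed, latent, name) {
  vars <- c(observed, latent)
  n <- length(vars)
  z <- matrix(0, n, n, dimnames = list(vars, vars))
  list(vars = vars, observed = c(rep(TRUE, length(observed)),
                                 rep(FALSE, length(latent))),
       A = z, A_free = z > 0, S = z, S_free = z > 0, name = name)
}

add_factor <- function(m, latent, indicators, marker = TRUE) {
  for (k in seq_along(indicators)) {
    if (marker && k == 1L) m$A[indicators[k], latent] <- 1
    else m$A_free[indicators[k], latent] <- TRUE
  }
  m$S_free[latent, latent] <- TRUE
  m
}

add_regression <- function(m, to, from) {
  for (f in from) m$A_free[to, f] <- TRUE
  m
}

add_variance <- function(m, v) {
  for (x in v) m$S_free[x, x] <- TRUE
  m
}

add_covariance <- function(m, v1, v2) {
  m$S_free[v1, v2] <- m$S_free[v2, v1] <- TRUE
  m
}

finish_ram <- function(m) {
  ram_spec(m$vars, m$observed, m$A, m$A_free, m$S, m$S_free, m$name)
}

# --- concrete models ----------------------------------------------------

#' Higher-order three-factor model of the simulated battery (Model 1)
#'
#' Nine observed test scores load three-per-factor on fluid, verbal and
#' spatial first-order factors; the three factors load on a second-order
#' general factor g. No cross-loadings, uncorrelated residuals. Latents are
#' scaled by the marker rule (first loading fixed to 1); with nine observed
#' variables and 21 free parameters the model has 24 degrees of freedom.
#'
#' @param tests character vector of the nine broad test names, ordered
#'   fluid, verbal, spatial (three each).
#' @return A `potsem_spec`.
#' @export
model1_spec <- function(tests = c("Gf1", "Gf2", "Gf3", "Vb1", "Vb2", "Vb3",
                                  "Sp1", "Sp2", "Sp3")) {
  stopifnot(length(tests) == 9)
  m <- new_ram(tests, c("fluid", "verbal", "spatial", "g"), "model1")
  m <- add_factor(m, "fluid", tests[1:3])
  m <- add_factor(m, "verbal", tests[4:6])
  m <- add_factor(m, "spatial", tests[7:9])
  m <- add_factor(m, "g", c("fluid", "verbal", "spatial"))
  m <- add_variance(m, tests)   # residual variances
  finish_ram(m)
}

#' Model 1 plus manifest executive function predictors of g (Model 2)
#'
#' Extends [model1_spec()] with three observed executive function task
#' scores as exogenous regression predictors of the second-order g factor.
#' Their mutual covariances are fixed to zero — the executive attention
#' processes behind them are posited to be orthogonal — so each predictor
#' can only claim unique variance in g. The g disturbance stays free. With
#' twelve observed variables and 27 free parameters the model has 51
#' degrees of freedom.
#'
#' @param tests the nine broad test names (see [model1_spec()]).
#' @param ef_tests the three executive function task names
#'   (inhibition, updating, shifting).
#' @return A `potsem_spec`.
#' @export
model2_spec <- function(tests = c("Gf1", "Gf2", "Gf3", "Vb1", "Vb2", "Vb3",
                                  "Sp1", "Sp2", "Sp3"),
                        ef_tests = c("Inh", "Upd", "Shf")) {
  stopifnot(length(tests) == 9, length(ef_tests) == 3)
  m <- new_ram(c(tests, ef_tests),
               c("fluid", "verbal", "spatial", "g"), "model2")
  m <- add_factor(m, "fluid", tests[1:3])
  m <- add_factor(m, "verbal", tests[4:6])
  m <- add_factor(m, "spatial", tests[7:9])
  m <- add_factor(m, "g", c("fluid", "verbal", "spatial"))
  m <- add_variance(m, tests)       # residuals of broad tests
  m <- add_variance(m, ef_tests)    # EF variances; EF covariances stay 0
  m <- add_regression(m, "g", ef_tests)
  finish_ram(m)
}

#' Executive-function-to-g structural model for correlation-matrix input
#'
#' Task indicators load on latent updating, inhibition and shifting factors,
#' which jointly predict general intelligence — either a latent g measured
#' by its own indicators (when `criterion` names several variables) or a
#' single manifest composite score. By default the three executive function
#' factors are orthogonal (covariances fixed at zero), mirroring the
#' simulated battery's structural model, so that each factor's path carries
#' unique variance; set `ef_correlations = "free"` to estimate their
#' intercorrelations.
#'
#' @param factors named list mapping each executive function factor name to
#'   its character vector of indicator names.
#' @param criterion character vector: several indicator names (latent g) or
#'   one composite score name (manifest criterion).
#' @param ef_correlations `"orthogonal"` (default) or `"free"`.
#' @param name model label.
#' @return A `potsem_spec`.
#' @examples
#' spec <- study2_spec(
#'   factors = list(updating = c("U1", "U2", "U3"),
#'                  inhibition = c("I1", "I2", "I3"),
#'                  shifting = c("S1", "S2", "S3")),
#'   criterion = c("G1", "G2", "G3"))
#' spec  # df = 51
#' @export
study2_spec <- function(factors, criterion,
                        ef_correlations = c("orthogonal", "free"),
                        name = "study2") {
  ef_correlations <- match.arg(ef_correlations)
  stopifnot(is.list(factors), length(factors) >= 1,
            !is.null(names(factors)), length(criterion) >= 1)
  indicators <- unlist(factors, use.names = FALSE)
  if (anyDuplicated(c(indicators, criterion)))
    stop("indicator names must be unique across factors and criterion",
         call. = FALSE)
  latent_g <- length(criterion) > 1
  obs <- c(indicators, criterion)
  lat <- c(names(factors), if (latent_g) "g")
  m <- new_ram(obs, lat, name)
  for (f in names(factors)) m <- add_factor(m, f, factors[[f]])
  m <- add_variance(m, indicators)
  if (latent_g) {
    m <- add_factor(m, "g", criterion)
    m <- add_variance(m, criterion)
    gvar <- "g"
  } else {
    m <- add_variance(m, criterion)   # residual variance of the composite
    gvar <- criterion
  }
  m <- add_regression(m, gvar, names(factors))
  if (ef_correlations == "free" && length(factors) > 1) {
    pairs <- utils::combn(names(factors), 2)
    for (k in seq_len(ncol(pairs)))
      m <- add_covariance(m, pairs[1, k], pairs[2, k])
  }
  finish_ram(m)
}

#' Serialize / restore a model specification
#'
#' Writes the full RAM representation (variables, observed flags, fixed
#' values and free-parameter patterns) as JSON; `sem_spec_from_json`
#' restores an identical specification.
#'
#' @param spec a `potsem_spec`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly); `sem_spec_from_json` returns
#'   the restored `potsem_spec`.
#' @export
sem_spec_to_json <- function(spec, path = NULL) {
  payload <- list(name = spec$name, vars = spec$vars,
                  observed = spec$observed,
                  A = spec$A, A_free = spec$A_free * 1L,
                  S = spec$S, S_free = spec$S_free * 1L)
  js <- jsonlite::toJSON(payload, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname sem_spec_to_json
#' @param json JSON string or path to a JSON file.
#' @export
sem_spec_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  ram_spec(payload$vars, payload$observed,
           payload$A, payload$A_free == 1,
           payload$S, payload$S_free == 1,
           name = payload$name)
}
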