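# Maximum-likelihood covariance-structure estimation for RAM models.
#
# The discrepancy minimized is the normal-theory ML fit function
#   F_ML = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^-1) - p
# with chi-square = (N - 1) * F_ML (Wishart convention, matching a sample
# covariance computed with the N - 1 denominator).

# Objective factory: returns fn (F_ML) and gr (its analytic gradient).
# For V = B S B' with B = (I - A)^-1 and W = Sigma^-1 - Sigma^-1 S Sigma^-1
# padded to all variables, dF/dA[i,j] = 2 (V W B)[j,i] and
# dF/dS[i,j] = (B' W B)[i,j] (doubled off-diagonal). The pieces computed at
# the last parameter value are cached so fn/gr pairs cost one evaluation.
ml_objective <- function(spec, S, logdetS) {
  p <- sum(spec$observed)
  n <- length(spec$vars)
  obs <- which(spec$observed)
  pt <- param_table(spec)
  na <- sum(pt$matrix == "A")
  s_diag <- pt$matrix == "S" & pt$row == pt$col
  a_lin <- attr(pt, "a_lin")
  s_lin <- attr(pt, "s_lin")
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  compute <- function(params) {
    if (!is.null(cache$par) && identical(params, cache$par))
      return(cache$state)
    mats <- fill_params(spec, params)
    B <- tryCatch(solve(diag(n) - mats$A), error = function(e) NULL)
    state <- list(ok = FALSE, value = 1e10)
    if (!is.null(B)) {
      V <- B %*% mats$S %*% t(B)
      Sigma <- V[obs, obs, drop = FALSE]
      ch <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (!is.null(ch) && all(is.finite(ch))) {
        Siginv <- chol2inv(ch)
        val <- 2 * sum(log(diag(ch))) - logdetS + sum(Siginv * S) - p
        if (is.finite(val))
          state <- list(ok = TRUE, value = val, B = B, V = V,
                        Siginv = Siginv)
      }
    }
    cache$par <- params
    cache$state <- state
    state
  }
  fn <- function(params) compute(params)$value
  gr <- function(params) {
    st <- compute(params)
    if (!st$ok) return(rep(0, nrow(pt)))
    W <- st$Siginv - st$Siginv %*% S %*% st$Siginv
    Wfull <- matrix(0, n, n)
    Wfull[obs, obs] <- W
    g <- numeric(nrow(pt))
    if (na > 0) {
      M <- t(st$V %*% Wfull %*% st$B)      # M[i, j] = (V W B)[j, i]
      g[seq_len(na)] <- 2 * M[a_lin]
    }
    if (nrow(pt) > na) {
      G <- t(st$B) %*% Wfull %*% st$B
      idx <- (na + 1L):nrow(pt)
      g[idx] <- G[s_lin] * ifelse(s_diag[idx], 1, 2)
    }
    g
  }
  list(fn = fn, gr = gr)
}

num_gradient <- function(fn, par, eps = 1e-6) {
  vapply(seq_along(par), function(k) {
    h <- eps * max(1, abs(par[k]))
    up <- par; up[k] <- up[k] + h
    dn <- par; dn[k] <- dn[k] - h
    (fn(up) - fn(dn)) / (2 * h)
  }, 0)
}

# Data-driven starting values: residual variances at half the sample
# variance, latent variances scaled through their marker chain, loadings at
# the SD ratio to the marker indicator, regressions at zero.
start_values <- function(spec, S) {
  pt <- param_table(spec)
  obs_names <- spec$vars[spec$observed]
  sample_sd <- function(v) {
    # follow fixed-1 marker loadings down to an observed variable
    seen <- character()
    while (!(v %in% obs_names)) {
      if (v %in% seen) return(1)
      seen <- c(seen, v)
      out <- which(spec$A[, v] == 1 & !spec$A_free[, v])
      if (length(out) == 0) return(1)
      v <- spec$vars[out[1]]
    }
    sqrt(S[v, v])
  }
  start <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    to <- spec$vars[pt$row[k]]
    from <- spec$vars[pt$col[k]]
    if (pt$matrix[k] == "A") {
      # paths out of latents start at a scale-matched loading so the
      # optimizer never sits on the all-zero stationary point; paths from
      # observed predictors start at zero
      start[k] <- if (!spec$observed[pt$col[k]])
        0.7 * sample_sd(to) / sample_sd(from) else 0
    } else if (pt$row[k] == pt$col[k]) {
      start[k] <- if (spec$observed[pt$row[k]])
        0.5 * S[to, to] else 0.4 * sample_sd(to)^2
    } else {
      start[k] <- 0
    }
  }
  start
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy between the sample covariance
#' matrix and the model-implied covariance with a quasi-Newton optimizer,
#' polishing until the improvement per pass falls below 1e-9 and flagging
#' convergence by the gradient norm. Non-converged solutions trigger up to
#' `max_restarts` jittered restarts and are flagged, never silently
#' returned. Negative residual-variance estimates (Heywood cases) are
#' permitted but reported in `warnings`; `constrain = TRUE` bounds all
#' variances at zero instead.
#'
#' @param spec a `potsem_spec` model.
#' @param S sample covariance matrix of the observed variables (a
#'   correlation matrix is treated as the covariance of standardized
#'   variables). Row/column names must cover the spec's observed variables.
#' @param N sample size behind `S`.
#' @param start optional numeric vector of starting values.
#' @param max_restarts jittered restarts after a non-converged run.
#' @param constrain lower-bound variances at zero (L-BFGS-B).
#' @return An object of class `potsem_fit`: estimates with labels, the
#'   minimized discrepancy `fml`, `chisq`, `df`, `p.value`, fit `indices`
#'   (see [fit_indices()]), `Sigma_hat`, `converged`, `warnings`.
#' @export
fit_ml <- function(spec, S, N, start = NULL, max_restarts = 5,
                   constrain = FALSE) {
  stopifnot(inherits(spec, "potsem_spec"))
  obs <- spec$vars[spec$observed]
  if (is.null(rownames(S))) {
    if (nrow(S) != length(obs))
      stop("S has wrong dimension and no variable names", call. = FALSE)
    dimnames(S) <- list(obs, obs)
  }
  if (!all(obs %in% rownames(S)))
    stop("S lacks observed variables: ",
         paste(setdiff(obs, rownames(S)), collapse = ", "), call. = FALSE)
  S <- as.matrix(S)[obs, obs]
  if (!isTRUE(all.equal(unname(S), unname(t(S)), tolerance = 1e-8)))
    stop("sample covariance matrix is not symmetric", call. = FALSE)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("sample covariance matrix is not positive definite ",
         "(smallest eigenvalue ", format(min(ev)), ")", call. = FALSE)
  p <- length(obs)
  if (N <= p) stop("N must exceed the number of observed variables",
                   call. = FALSE)
  logdetS <- sum(log(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  obj <- ml_objective(spec, S, logdetS)
  fn <- obj$fn
  gr <- obj$gr
  pt <- param_table(spec)
  if (is.null(start)) start <- start_values(spec, S)

  is_var <- pt$matrix == "S" & pt$row == pt$col
  run_opt <- function(par0) {
    if (constrain) {
      lower <- ifelse(is_var, 1e-8, -Inf)
      out <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = 2000, factr = 1e3))
    } else {
      out <- stats::optim(par0, fn, gr, method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-12))
      # polish: restart BFGS from the optimum until no further progress
      for (i in 1:3) {
        out2 <- stats::optim(out$par, fn, gr, method = "BFGS",
                             control = list(maxit = 2000, reltol = 1e-12))
        if (out$value - out2$value < 1e-9) { out <- out2; break }
        out <- out2
      }
    }
    out
  }
  best <- run_opt(start)
  grad_ok <- function(o) {
    if (constrain) return(o$convergence == 0 && o$value < 1e9)
    max(abs(gr(o$par))) < 1e-5 && o$value < 1e9
  }
  converged <- grad_ok(best)
  tries <- 0
  while (!converged && tries < max_restarts) {
    tries <- tries + 1
    jitter <- start * exp(stats::rnorm(length(start), 0, 0.25)) +
      stats::rnorm(length(start), 0, 0.05)
    cand <- run_opt(jitter)
    if (cand$value < best$value) best <- cand
    converged <- grad_ok(best)
  }

  est <- best$par
  names(est) <- pt$label
  fml <- max(best$value, 0)
  if (fml < 1e-12) fml <- 0
  df <- p * (p + 1) / 2 - nrow(pt)
  chisq <- (N - 1) * fml
  warnings <- character()
  vh <- est[is_var]
  if (any(vh < 0))
    warnings <- c(warnings, paste0("negative variance estimate (Heywood): ",
                                   paste(names(vh)[vh < 0], collapse = ", ")))
  fit <- structure(list(
    spec = spec, estimates = est, param_table = pt,
    Sigma_hat = implied_covariance(spec, best$par),
    S = S, N = N, fml = fml, chisq = chisq, df = df,
    p.value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
              else NA_real_,
    converged = converged, warnings = warnings), class = "potsem_fit")
  fit$indices <- fit_indices(fit)
  for (w in warnings) warning(w, call. = FALSE)
  fit
}

#' Fit indices for a fitted model
#'
#' Computes CFI against the independence baseline (all covariances zero,
#' variances free, whose ML solution is available in closed form), the
#' RMSEA point estimate `sqrt(max(chisq - df, 0) / (df (N - 1)))` with its
#' 90% confidence interval from [rmsea_ci()], and the SRMR over all unique
#' elements of the standardized residual matrix, diagonal included.
#'
#' @param fit a `potsem_fit`.
#' @param S,N override the sample covariance / size stored in the fit.
#' @return A list of class `potsem_indices`: `cfi`, `rmsea`, `rmsea_ci`
#'   (length-2), `srmr`, plus the baseline `chisq_baseline`/`df_baseline`.
#' @export
fit_indices <- function(fit, S = fit$S, N = fit$N) {
  p <- nrow(S)
  logdetS <- sum(log(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  f_base <- sum(log(diag(S))) - logdetS
  chisq_b <- (N - 1) * f_base
  df_b <- p * (p - 1) / 2
  d_m <- max(fit$chisq - fit$df, 0)
  d_b <- max(chisq_b - df_b, 0)
  cfi <- if (max(d_m, d_b) == 0) 1 else 1 - d_m / max(d_m, d_b)
  if (fit$df > 0) {
    rmsea <- sqrt(d_m / (fit$df * (N - 1)))
    ci <- rmsea_ci(fit$chisq, fit$df, N)
  } else {
    rmsea <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  Ds <- diag(1 / sqrt(diag(S)))
  Do <- diag(1 / sqrt(diag(fit$Sigma_hat)))
  res <- Ds %*% S %*% Ds - Do %*% fit$Sigma_hat %*% Do
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  structure(list(cfi = cfi, rmsea = rmsea, rmsea_ci = ci, srmr = srmr,
                 chisq_baseline = chisq_b, df_baseline = df_b),
            class = "potsem_indices")
}

#' RMSEA confidence interval by noncentral chi-square inversion
#'
#' Finds the noncentrality parameters at which the observed chi-square sits
#' at the 95th and 5th percentile of the noncentral chi-square distribution
#' (for a 90% interval) and converts them to the RMSEA scale via
#' `sqrt(lambda / (df (N - 1)))`; a bound with no root is 0.
#'
#' @param chisq observed chi-square statistic.
#' @param df model degrees of freedom.
#' @param N sample size.
#' @param level confidence level (default 0.90).
#' @return Numeric `c(lower, upper)`.
#' @examples
#' rmsea_ci(26.47, 24, 1000)   # about [0.00, 0.03]
#' @export
rmsea_ci <- function(chisq, df, N, level = 0.90) {
  if (df <= 0) return(c(NA_real_, NA_real_))
  alpha <- (1 - level) / 2
  solve_ncp <- function(target) {
    # lambda with pchisq(chisq, df, ncp = lambda) == target
    if (stats::pchisq(chisq, df) < target) return(0)
    hi <- max(chisq * 2, df + 10)
    while (stats::pchisq(chisq, df, ncp = hi) > target) hi <- hi * 2
    stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - target,
                   c(0, hi), tol = 1e-10)$root
  }
  lam_lo <- solve_ncp(1 - alpha)
  lam_hi <- solve_ncp(alpha)
  sqrt(c(lam_lo, lam_hi) / (df * (N - 1)))
}

#' Fully standardized solution
#'
#' Rescales every path and (co)variance so that all variables — observed
#' and latent — have unit variance; the result does not depend on the
#' identification rule used during estimation. A path from `x` to `y`
#' becomes `est * sd(x) / sd(y)`; a covariance becomes a correlation; a
#' residual variance becomes a proportion of total variance.
#'
#' @param fit a `potsem_fit`.
#' @return A data frame with columns `label`, `matrix`, `from`, `to`,
#'   `est`, `std`, free parameters and fixed marker loadings alike.
#' @export
standardized_solution <- function(fit) {
  spec <- fit$spec
  mats <- fill_params(spec, unname(fit$estimates))
  V <- ram_covariance(spec, unname(fit$estimates))
  sdv <- sqrt(pmax(diag(V), 0))
  rows <- list()
  a_idx <- which(spec$A_free | mats$A != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(a_idx))) {
    i <- a_idx[k, 1]; j <- a_idx[k, 2]
    rows[[length(rows) + 1]] <- data.frame(
      label = paste0(spec$vars[j], "->", spec$vars[i]), matrix = "A",
      from = spec$vars[j], to = spec$vars[i], est = mats$A[i, j],
      std = if (sdv[i] > 0) mats$A[i, j] * sdv[j] / sdv[i] else NA_real_)
  }
  s_idx <- which((spec$S_free | mats$S != 0) &
                   lower.tri(mats$S, diag = TRUE), arr.ind = TRUE)
  for (k in seq_len(nrow(s_idx))) {
    i <- s_idx[k, 1]; j <- s_idx[k, 2]
    denom <- sdv[i] * sdv[j]
    rows[[length(rows) + 1]] <- data.frame(
      label = paste0(spec$vars[i], "~~", spec$vars[j]), matrix = "S",
      from = spec$vars[j], to = spec$vars[i], est = mats$S[i, j],
      std = if (denom > 0) mats$S[i, j] / denom else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression-method factor scores
#'
#' Computes per-person scores for a latent variable with the regression
#' (Thurstone) estimator: weights are the inverse model-implied covariance
#' of the observed variables times their implied covariance with the
#' latent, applied to centered observed scores. Scores have mean zero.
#'
#' @param fit a `potsem_fit`.
#' @param data numeric matrix/data frame of observed scores with column
#'   names covering the model's observed variables.
#' @param latent name of the latent variable (default `"g"`).
#' @return Numeric vector of factor scores, one per row of `data`.
#' @export
factor_scores <- function(fit, data, latent = "g") {
  spec <- fit$spec
  obs <- spec$vars[spec$observed]
  if (!latent %in% spec$vars[!spec$observed])
    stop("no latent variable named '", latent, "'", call. = FALSE)
  X <- as.matrix(as.data.frame(data)[, obs, drop = FALSE])
  V <- ram_covariance(spec, unname(fit$estimates))
  w <- solve(fit$Sigma_hat, V[obs, latent])
  drop(scale(X, center = TRUE, scale = FALSE) %*% w)
}

#' @export
print.potsem_fit <- function(x, ...) {
  cat("ML fit of '", x$spec$name, "' (N = ", x$N, ")\n", sep = "")
  cat(sprintf("  chisq(%d) = %.2f, p = %.3f, F_ML = %.6f%s\n",
              x$df, x$chisq, x$p.value %||% NA, x$fml,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  ci <- x$indices$rmsea_ci
  cat(sprintf("  CFI = %.3f, RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f\n",
              x$indices$cfi, x$indices$rmsea, ci[1], ci[2],
              x$indices$srmr))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
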