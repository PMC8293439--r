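#' R-squared of a predictor-subset regression
#'
#' Ordinary least-squares coefficient of determination of the criterion on
#' the selected columns of the predictor matrix (intercept included).
#'
#' @param y numeric criterion vector.
#' @param X numeric predictor matrix.
#' @param subset integer or character index of the columns to enter.
#' @return R-squared in \[0, 1\].
#' @export
subset_r2 <- function(y, X, subset) {
  X <- as.matrix(X)
  if (length(subset) < 1) stop("subset must be non-empty", call. = FALSE)
  Xs <- X[, subset, drop = FALSE]
  if (any(apply(Xs, 2, stats::sd) == 0))
    stop("constant predictor in subset: ",
         paste(colnames(Xs)[apply(Xs, 2, stats::sd) == 0], collapse = ", "),
         call. = FALSE)
  Z <- cbind(1, Xs)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop("singular design: predictors ",
         paste(colnames(Xs), collapse = ", "), " are collinear",
         call. = FALSE)
  res <- stats::lm.fit(Z, y)$residuals
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Assemble a three-predictor decomposition from the 7 subset R^2 values,
# named "A","B","C","AB","AC","BC","ABC".
commonality_components <- function(r2, labels) {
  u <- c(r2[["ABC"]] - r2[["BC"]],
         r2[["ABC"]] - r2[["AC"]],
         r2[["ABC"]] - r2[["AB"]])
  s2 <- c(r2[["AC"]] + r2[["BC"]] - r2[["ABC"]] - r2[["C"]],
          r2[["AB"]] + r2[["BC"]] - r2[["ABC"]] - r2[["B"]],
          r2[["AB"]] + r2[["AC"]] - r2[["ABC"]] - r2[["A"]])
  s3 <- r2[["A"]] + r2[["B"]] + r2[["C"]] -
    r2[["AB"]] - r2[["AC"]] - r2[["BC"]] + r2[["ABC"]]
  names(u) <- paste0("unique_", labels)
  names(s2) <- paste0("shared_", c(paste0(labels[1], "_", labels[2]),
                                   paste0(labels[1], "_", labels[3]),
                                   paste0(labels[2], "_", labels[3])))
  out <- structure(list(unique = u, shared_pairwise = s2,
                        shared_all = s3, r2_full = r2[["ABC"]],
                        subset_r2 = r2, labels = labels),
                   class = "pot_commonality")
  if (any(c(s2, s3) < -1e-10))
    warning("negative shared variance component (suppression); ",
            "reported as-is", call. = FALSE)
  out
}

#' Commonality analysis for three predictors
#'
#' Decomposes the variance a criterion shares with three predictors into
#' seven components — three unique, three pairwise-shared and one shared by
#' all — from the R-squared values of all seven predictor subsets (the
#' quantities generated by entering the predictors into hierarchical
#' regressions in all six possible orders). The unique contribution of A is
#' R2(ABC) - R2(BC); the A-B shared contribution is
#' R2(AC) + R2(BC) - R2(ABC) - R2(C); and so on cyclically. Components sum
#' exactly to the full-model R-squared. Shared components can be negative
#' under suppression and are reported as-is with a warning.
#'
#' @param y criterion vector.
#' @param x1,x2,x3 predictor vectors.
#' @param labels names used in the output components.
#' @return An object of class `pot_commonality` with elements `unique`,
#'   `shared_pairwise`, `shared_all`, `r2_full` and the seven `subset_r2`.
#' @export
commonality <- function(y, x1, x2, x3,
                        labels = c(deparse(substitute(x1)),
                                   deparse(substitute(x2)),
                                   deparse(substitute(x3)))) {
  X <- cbind(A = x1, B = x2, C = x3)
  if (length(y) != nrow(X)) stop("inputs differ in length", call. = FALSE)
  if (nrow(X) <= 10) stop("need more than 10 observations", call. = FALSE)
  sets <- list(A = 1, B = 2, C = 3, AB = c(1, 2), AC = c(1, 3),
               BC = c(2, 3), ABC = 1:3)
  r2 <- vapply(sets, function(s) subset_r2(y, X, s), 0)
  commonality_components(r2, labels)
}

#' Commonality analysis from a correlation structure
#'
#' Identical decomposition to [commonality()] for any dataset having
#' exactly the supplied second moments: each subset R-squared is the
#' quadratic form `r' R^-1 r` of the criterion validities on the inverse
#' predictor-correlation submatrix. Useful for latent-level decompositions,
#' where the predictor correlations and validities come from a fitted
#' structural model rather than raw data.
#'
#' @param R_xx 3x3 predictor correlation matrix.
#' @param r_xy length-3 vector of predictor-criterion correlations.
#' @param labels names used in the output components.
#' @return A `pot_commonality`.
#' @export
commonality_from_correlations <- function(R_xx, r_xy,
                                          labels = colnames(R_xx) %||%
                                            c("A", "B", "C")) {
  R_xx <- as.matrix(R_xx)
  stopifnot(all(dim(R_xx) == 3), length(r_xy) == 3)
  if (!isTRUE(all.equal(unname(R_xx), unname(t(R_xx)))))
    stop("R_xx must be symmetric", call. = FALSE)
  ev <- eigen(R_xx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("R_xx is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  sets <- list(A = 1, B = 2, C = 3, AB = c(1, 2), AC = c(1, 3),
               BC = c(2, 3), ABC = 1:3)
  r2 <- vapply(sets, function(s) {
    r <- r_xy[s]
    drop(crossprod(r, solve(R_xx[s, s, drop = FALSE], r)))
  }, 0)
  commonality_components(r2, labels)
}

#' @export
print.pot_commonality <- function(x, digits = 4, ...) {
  cat("Commonality decomposition (full-model R2 =",
      round(x$r2_full, digits), ")\n")
  comp <- c(x$unique, x$shared_pairwise, shared_all = x$shared_all)
  print(round(comp, digits))
  invisible(x)
}

#' Tidy a commonality decomposition
#'
#' @param x a `pot_commonality`.
#' @return A data frame with columns `component` and `value` (the seven
#'   components plus the full-model R-squared).
#' @export
commonality_table <- function(x) {
  stopifnot(inherits(x, "pot_commonality"))
  data.frame(
    component = c(names(x$unique), names(x$shared_pairwise),
                  "shared_all", "r2_full"),
    value = unname(c(x$unique, x$shared_pairwise, x$shared_all, x$r2_full)))
}
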