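# Small-scale configuration for unit tests: enough subjects for stable SEM
# fits, few enough items to keep simulation cheap.
tiny_config <- function(n_subjects = 400, n_items = 30, seed = 1L,
                        n_iterations = 2L) {
  sim_config(n_subjects = n_subjects, n_items_per_test = n_items,
             n_iterations = n_iterations, master_seed = seed)
}

# Population covariance of a one-factor model with given loadings and unit
# factor variance, residuals completing unit total variance.
one_factor_cov <- function(loadings) {
  S <- tcrossprod(loadings)
  diag(S) <- 1
  S
}

# Hand-coded population covariance of an executive-function structural
# model: three orthogonal EF factors (variance 1) with given loadings, a
# latent g with disturbance psi regressed on the factors, and g indicators.
# Independent of the package's RAM machinery.
ef_population_cov <- function(ef_loadings, g_loadings, beta, psi,
                              resid_ind, resid_g) {
  # variables: 9 EF indicators, then 3 g indicators
  Lam <- matrix(0, 9, 3)
  Lam[1:3, 1] <- ef_loadings[[1]]
  Lam[4:6, 2] <- ef_loadings[[2]]
  Lam[7:9, 3] <- ef_loadings[[3]]
  var_g <- sum(beta^2) + psi          # factors orthogonal, variance 1
  cov_f_g <- beta                     # cov(F_j, g) = beta_j
  S <- matrix(0, 12, 12)
  S[1:9, 1:9] <- Lam %*% t(Lam)
  S[1:9, 10:12] <- Lam %*% cov_f_g %*% t(g_loadings)
  S[10:12, 1:9] <- t(S[1:9, 10:12])
  S[10:12, 10:12] <- var_g * tcrossprod(g_loadings)
  diag(S)[1:9] <- diag(S)[1:9] + resid_ind
  diag(S)[10:12] <- diag(S)[10:12] + resid_g
  S
}
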