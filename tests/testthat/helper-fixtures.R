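# small cohort configurations used across tests

small_cohort_config <- function(seed = 1L, ...) {
  cohort_sim_config(genes = c(concordant_up = 10, mrna_down_protein_up = 5,
                              mrna_up_protein_down = 5, concordant_down = 10,
                              mediated = 10, null = 20),
                    seed = seed, ...)
}

null_cohort_config <- function(n_genes, seed = 1L, bio_sd = 0, ...) {
  cohort_sim_config(n_male = rep(32, 3), n_female = rep(32, 3),
                    genes = c(concordant_up = 0, mrna_down_protein_up = 0,
                              mrna_up_protein_down = 0, concordant_down = 0,
                              mediated = 0, null = n_genes),
                    sex_sd = 0, batch_sd = 0, bio_sd = bio_sd, seed = seed, ...)
}

rank_normal_rows <- function(m) t(apply(m, 1, rank_normal_transform))

# independent dense-matrix oracle for the profiled Gaussian log-likelihood of
# a random-intercept model at fixed variance ratios: builds V explicitly,
# does closed-form GLS, no Woodbury shortcuts
dense_lmm_loglik <- function(y, X, factors, gammas) {
  n <- length(y)
  V <- diag(n)
  for (k in seq_along(factors)) {
    Z <- model.matrix(~ 0 + factor(factors[[k]]))
    V <- V + gammas[k] * tcrossprod(Z)
  }
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Vi %*% r) / n
  as.numeric(-0.5 * n * (log(2 * pi * sigma2) + 1) -
               0.5 * determinant(V)$modulus)
}

# independent Poisson GLM fitted by hand-rolled IRLS with an offset
poisson_irls <- function(y, X, offset, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y)) - mean(offset)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- mu
    z <- eta - offset + (y - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- exp(drop(X %*% beta) + offset)
  list(beta = drop(beta), loglik = sum(stats::dpois(y, mu, log = TRUE)))
}
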