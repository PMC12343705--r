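# Shared fixtures and independent oracle implementations.  The oracles are
# deliberately naive (loops, direct formula transcription) so that they stay
# independent of the vectorised code paths they check.

# Small two-class parameter set with distinct, hand-picked values.
tiny_params <- function(J = 5, C = 2, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    mixtree_params(
      alpha_trait = runif(J, 0.6, 1.2),
      beta1 = rnorm(J, 0, 0.8),
      omega = matrix(runif(J * C, 0.2, 0.9), J, C),
      alpha_ers = seq(1.1, 0.5, length.out = C),
      beta2 = matrix(rnorm(J * C, 0, 0.8), J, C),
      beta3 = matrix(rnorm(J * C, 0, 0.8), J, C),
      pi = rep(1 / C, C),
      latent_corr = 0.2)
  })
}

# Parameter set whose node probabilities are all plogis(beta): loadings are
# (numerically) zero so the latent variables drop out of the likelihood.
flat_params <- function(beta1, beta2, beta3, pi = 1, C = length(pi)) {
  J <- length(beta1)
  eps <- 1e-9
  mixtree_params(rep(eps, J), beta1,
                 omega = matrix(0, J, C),
                 alpha_ers = rep(eps, C),
                 beta2 = matrix(beta2, J, C), beta3 = matrix(beta3, J, C),
                 pi = pi, latent_corr = 0)
}

# Naive per-person class-conditional log-likelihood: loops over items and
# multiplies the Table-style node terms one by one.
naive_loglik_given_class <- function(params, responses, theta, eta, class_id) {
  y <- as.matrix(responses)
  out <- numeric(nrow(y))
  for (p in seq_len(nrow(y))) {
    ll <- 0
    for (j in seq_len(ncol(y))) {
      cat_ <- y[p, j]
      if (is.na(cat_)) next
      pr <- node_probabilities(params, theta[p], eta[p], j, class_id)
      y1 <- as.numeric(cat_ >= 3)
      ll <- ll + y1 * log(pr[, "p1"]) + (1 - y1) * log(1 - pr[, "p1"])
      if (cat_ <= 2) {
        y2 <- as.numeric(cat_ == 2)
        ll <- ll + y2 * log(pr[, "p2"]) + (1 - y2) * log(1 - pr[, "p2"])
      } else {
        y3 <- as.numeric(cat_ == 4)
        ll <- ll + y3 * log(pr[, "p3"]) + (1 - y3) * log(1 - pr[, "p3"])
      }
    }
    out[p] <- ll
  }
  out
}

# Monte-Carlo marginal log-likelihood for one person: averages the mixture
# likelihood over fresh bivariate-normal draws.  Returns the estimate and
# its standard error on the log scale (delta method).
mc_marginal_loglik <- function(params, responses, person, n_draws = 2e5,
                               seed = 1) {
  set.seed(seed)
  theta <- rnorm(n_draws)
  eta <- params$latent_corr * theta +
    sqrt(1 - params$latent_corr^2) * rnorm(n_draws)
  y <- as.matrix(responses)[person, , drop = FALSE]
  lik <- 0
  for (cc in seq_len(params$C)) {
    ll_c <- naive_loglik_vectorised(params, y, theta, eta, cc)
    lik <- lik + params$pi[cc] * exp(ll_c)
  }
  est <- mean(lik)
  se <- sd(lik) / sqrt(n_draws)
  list(loglik = log(est), se = se / est)
}

# Vectorised-over-draws version of the naive conditional likelihood (one
# response row, many latent draws); still independent of the package's
# matrix machinery.
naive_loglik_vectorised <- function(params, y_row, theta, eta, class_id) {
  ll <- numeric(length(theta))
  for (j in seq_len(ncol(y_row))) {
    cat_ <- y_row[1, j]
    if (is.na(cat_)) next
    a <- params$alpha_trait[j]
    p1 <- plogis(a * theta + params$beta1[j])
    aw <- a * params$omega[j, class_id]
    e <- params$alpha_ers[class_id]
    if (cat_ <= 2) {
      p2 <- plogis(aw * theta - e * eta + params$beta2[j, class_id])
      ll <- ll + log(1 - p1) + if (cat_ == 2) log(p2) else log(1 - p2)
    } else {
      p3 <- plogis(aw * theta + e * eta + params$beta3[j, class_id])
      ll <- ll + log(p1) + if (cat_ == 4) log(p3) else log(1 - p3)
    }
  }
  ll
}

# Minimal object that predict.mixtree() accepts, for scoring data under
# known parameters without running the optimiser.
fake_fit <- function(params, quad_points = 21) {
  structure(list(params = params, C = params$C, J = params$J,
                 quad_points = quad_points),
            class = "mixtree")
}
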