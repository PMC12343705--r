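test_that("conditional log-likelihood counts one node per branch", {
  # single item answered "4": direction + agreement-extremity nodes active,
  # both with probability 1/2 under flat parameters
  p <- flat_params(0, 0, 0)
  expect_equal(loglik_given_class(p, matrix(4), 0, 0, 1), log(0.25),
               tolerance = 1e-12)
  # category "1" likewise activates two nodes on the other branch
  expect_equal(loglik_given_class(p, matrix(1), 0, 0, 1), log(0.25),
               tolerance = 1e-12)
})

test_that("conditional log-likelihood is additive over items", {
  pars <- tiny_params(J = 2)
  item_slice <- function(p, j)
    mixtree_params(p$alpha_trait[j], p$beta1[j],
                   p$omega[j, , drop = FALSE], p$alpha_ers,
                   p$beta2[j, , drop = FALSE], p$beta3[j, , drop = FALSE],
                   p$pi, p$latent_corr)
  y <- matrix(c(2, 4), 1)
  both <- loglik_given_class(pars, y, 0.7, -0.3, 1)
  one <- loglik_given_class(item_slice(pars, 1), y[, 1, drop = FALSE], 0.7, -0.3, 1)
  two <- loglik_given_class(item_slice(pars, 2), y[, 2, drop = FALSE], 0.7, -0.3, 1)
  expect_equal(both, one + two, tolerance = 1e-12)
})

test_that("conditional log-likelihood matches the naive node-product oracle", {
  pars <- tiny_params(J = 5, C = 2)
  set.seed(11)
  y <- matrix(sample(1:4, 40, replace = TRUE), 8, 5)
  y[2, 3] <- NA
  theta <- rnorm(8); eta <- rnorm(8)
  for (cc in 1:2) {
    expect_equal(loglik_given_class(pars, y, theta, eta, cc),
                 naive_loglik_given_class(pars, y, theta, eta, cc),
                 tolerance = 1e-10)
  }
})

test_that("marginal likelihood without latent dependence is quadrature-free", {
  b1 <- c(0.3, -0.5, 1); b2 <- c(0, 0.4, -0.2); b3 <- c(0.8, 0, -1)
  p <- flat_params(b1, b2, b3)
  y <- matrix(c(1, 3, 4), 1)
  manual <- log(1 - plogis(b1[1])) + log(1 - plogis(b2[1])) +
    log(plogis(b1[2])) + log(1 - plogis(b3[2])) +
    log(plogis(b1[3])) + log(plogis(b3[3]))
  expect_equal(as.vector(marginal_loglik(p, y, 5)), manual, tolerance = 1e-8)
  expect_equal(as.vector(marginal_loglik(p, y, 15)),
               as.vector(marginal_loglik(p, y, 5)), tolerance = 1e-8)
})

test_that("a mixture of identical classes collapses to the single class", {
  pars1 <- tiny_params(J = 4, C = 1)
  for (pi1 in c(0.5, 0.9)) {
    pars2 <- mixtree_params(pars1$alpha_trait, pars1$beta1,
                            cbind(pars1$omega, pars1$omega),
                            rep(pars1$alpha_ers, 2),
                            cbind(pars1$beta2, pars1$beta2),
                            cbind(pars1$beta3, pars1$beta3),
                            pi = c(pi1, 1 - pi1),
                            latent_corr = pars1$latent_corr)
    set.seed(12)
    y <- matrix(sample(1:4, 24, replace = TRUE), 6, 4)
    expect_equal(as.vector(marginal_loglik(pars2, y, 11)),
                 as.vector(marginal_loglik(pars1, y, 11)), tolerance = 1e-10)
  }
})

test_that("quadrature marginal agrees with Monte-Carlo integration", {
  pars <- tiny_params(J = 3, C = 2)
  set.seed(13)
  y <- matrix(sample(1:4, 9, replace = TRUE), 3, 3)
  ll <- marginal_loglik(pars, y, 15)
  for (p in 1:3) {
    mc <- mc_marginal_loglik(pars, y, p, n_draws = 2e5, seed = 100 + p)
    expect_lt(abs(ll[p] - mc$loglik), 3 * mc$se)
  }
})

test_that("single-class marginal matches an independent fine-grid integration", {
  # traditional IRTree special case: brute-force 2-D trapezoid integration
  # over the latent density, fully independent of the Gauss-Hermite code
  pars <- tiny_params(J = 4, C = 1)
  set.seed(14)
  y <- matrix(sample(1:4, 12, replace = TRUE), 3, 4)
  gx <- seq(-6, 6, length.out = 241)
  h <- diff(gx[1:2])
  rho <- pars$latent_corr
  ll_ref <- vapply(seq_len(nrow(y)), function(p) {
    tot <- 0
    for (t_ in gx) {
      lc <- naive_loglik_vectorised(pars, y[p, , drop = FALSE],
                                    rep(t_, length(gx)), gx, 1L)
      dens <- dnorm(t_) * dnorm((gx - rho * t_) / sqrt(1 - rho^2)) /
        sqrt(1 - rho^2)
      tot <- tot + sum(exp(lc) * dens) * h * h
    }
    log(tot)
  }, numeric(1))
  expect_equal(as.vector(marginal_loglik(pars, y, 21)), ll_ref,
               tolerance = 1e-6)
})

test_that("marginal likelihood stays finite for extreme response vectors", {
  pars <- tiny_params(J = 6, C = 2)
  y <- rbind(rep(4, 6), rep(1, 6), rep(2, 6))
  ll <- marginal_loglik(pars, y, 15)
  expect_true(all(is.finite(ll)))
})

test_that("the EM gradient machinery matches numerical differentiation", {
  set.seed(15)
  y <- matrix(sample(1:4, 60, replace = TRUE), 12, 5)
  ind <- mixtree:::pseudo_indicators(pseudo_items(y))
  obj <- mixtree:::make_objective(ind, 2L, 5L, 5L, estimate_corr = TRUE)
  pars <- tiny_params(J = 5, C = 2)
  v <- mixtree:::pack_params(pars, TRUE)
  expect_equal(obj$gr(v), pracma::grad(obj$fn, v), tolerance = 1e-6)
  # M-step objective gradient (fixed expected counts)
  grid <- quadrature_grid(5, 0)
  marg <- mixtree:::mixture_marginal(ind, pars, grid, posterior = TRUE)
  counts <- mixtree:::expected_counts(ind, marg$R, 2L, length(grid$w))
  qobj <- mixtree:::make_q_objective(counts, 2L, 5L, grid, TRUE)
  vi <- mixtree:::pack_items(pars, TRUE)
  expect_equal(qobj$gr(vi), pracma::grad(qobj$fn, vi), tolerance = 1e-6)
})
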