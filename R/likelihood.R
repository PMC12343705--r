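## Likelihood machinery.
##
## All person-level quantities are computed on an N x Q grid per class, with
## Q quadrature nodes, via matrix products between 0/1 pseudo-item indicator
## matrices (N x J) and J x Q log-probability matrices.  log p and log(1-p)
## are evaluated through plogis(±l, log.p = TRUE), which is underflow-safe.

## J x Q log/response probabilities for the three nodes of one class.
node_matrices <- function(params, grid, class_id, want_p = FALSE) {
  J <- params$J
  Q <- length(grid$theta)
  a <- params$alpha_trait
  l1 <- outer(a, grid$theta) + params$beta1
  aw <- a * params$omega[, class_id]
  e <- params$alpha_ers[class_id]
  eEta <- matrix(e * grid$eta, J, Q, byrow = TRUE)
  base <- outer(aw, grid$theta)
  l2 <- base - eEta + params$beta2[, class_id]
  l3 <- base + eEta + params$beta3[, class_id]
  out <- list(lp1 = plogis(l1, log.p = TRUE), lq1 = plogis(-l1, log.p = TRUE),
              lp2 = plogis(l2, log.p = TRUE), lq2 = plogis(-l2, log.p = TRUE),
              lp3 = plogis(l3, log.p = TRUE), lq3 = plogis(-l3, log.p = TRUE))
  if (want_p) {
    out$P1 <- plogis(l1); out$P2 <- plogis(l2); out$P3 <- plogis(l3)
  }
  out
}

## N x Q conditional log-likelihood matrices, one per class.
class_loglik_matrices <- function(ind, params, grid) {
  nm1 <- NULL
  out <- vector("list", params$C)
  for (cc in seq_len(params$C)) {
    nm <- node_matrices(params, grid, cc)
    if (is.null(nm1)) {
      nm1 <- ind$A1 %*% nm$lp1 + ind$B1 %*% nm$lq1  # class-invariant node 1
    }
    out[[cc]] <- nm1 +
      ind$A2 %*% nm$lp2 + ind$B2 %*% nm$lq2 +
      ind$A3 %*% nm$lp3 + ind$B3 %*% nm$lq3
  }
  out
}

## Joint posterior machinery over (class, quadrature node).
## Returns per-person marginal log-likelihood and, on request, the
## N x (C*Q) posterior weight matrix.
mixture_marginal <- function(ind, params, grid, posterior = FALSE) {
  Ls <- class_loglik_matrices(ind, params, grid)
  Q <- length(grid$w)
  lw <- log(grid$w)
  lpi <- log(params$pi)
  NB <- do.call(cbind, lapply(seq_len(params$C), function(cc) {
    sweep(Ls[[cc]], 2, lw, `+`) + lpi[cc]
  }))
  m <- NB[cbind(seq_len(nrow(NB)), max.col(NB, ties.method = "first"))]
  E <- exp(NB - m)
  S <- rowSums(E)
  ll <- m + log(S)
  res <- list(ll = ll, C = params$C, Q = Q)
  if (posterior) res$R <- E / S
  res
}

#' Marginal person log-likelihoods
#'
#' Log of the mixture marginal likelihood of each respondent: the class
#' proportions weight class-conditional likelihoods in which the latent
#' trait/ERS pair is integrated out over a Gauss-Hermite product grid.
#' Structurally missing pseudo-items contribute nothing.
#'
#' @param params a [mixtree_params()] object.
#' @param responses response matrix (entries 1-4 or `NA`) or a
#'   `"pseudo_items"` object.
#' @param quad_points quadrature nodes per latent dimension.
#' @return Length-N vector of log-likelihoods with attribute `"total"`.
#' @export
marginal_loglik <- function(params, responses, quad_points = 15L) {
  pseudo <- if (inherits(responses, "pseudo_items")) responses else pseudo_items(responses)
  ind <- pseudo_indicators(pseudo)
  grid <- quadrature_grid(quad_points, params$latent_corr)
  ll <- mixture_marginal(ind, params, grid)$ll
  attr(ll, "total") <- sum(ll)
  ll
}

#' Class-conditional log-likelihood at fixed latent scores
#'
#' Sum over items of Bernoulli log-likelihoods of the observed pseudo-items
#' for given latent scores and class, i.e. the log of the inner product term
#' of the mixture likelihood before integration.
#'
#' @inheritParams marginal_loglik
#' @param theta,eta latent scores; scalars or length-N vectors.
#' @param class_id class index.
#' @return Length-N vector of conditional log-likelihoods.
#' @export
loglik_given_class <- function(params, responses, theta, eta, class_id = 1L) {
  pseudo <- if (inherits(responses, "pseudo_items")) responses else pseudo_items(responses)
  ind <- pseudo_indicators(pseudo)
  N <- ind$N
  theta <- rep_len(theta, N); eta <- rep_len(eta, N)
  a <- params$alpha_trait
  l1 <- outer(theta, a) + rep(params$beta1, each = N)          # N x J
  aw <- a * params$omega[, class_id]
  e <- params$alpha_ers[class_id]
  base <- outer(theta, aw)
  l2 <- base - outer(e * eta, rep(1, params$J)) + rep(params$beta2[, class_id], each = N)
  l3 <- base + outer(e * eta, rep(1, params$J)) + rep(params$beta3[, class_id], each = N)
  rowSums(ind$A1 * plogis(l1, log.p = TRUE) + ind$B1 * plogis(-l1, log.p = TRUE) +
          ind$A2 * plogis(l2, log.p = TRUE) + ind$B2 * plogis(-l2, log.p = TRUE) +
          ind$A3 * plogis(l3, log.p = TRUE) + ind$B3 * plogis(-l3, log.p = TRUE))
}

## ---- parameter packing for optimisation ----------------------------------
## Layout: log(alpha_trait) [J], beta1 [J], pi logits [C-1, class 1 ref],
## per class: omega [J], log(alpha_ers) [1], beta2 [J], beta3 [J],
## and finally atanh(latent_corr) [1] when the correlation is estimated.

pack_params <- function(params, estimate_corr = TRUE) {
  v <- c(log(params$alpha_trait), params$beta1)
  if (params$C > 1) v <- c(v, log(params$pi[-1]) - log(params$pi[1]))
  for (cc in seq_len(params$C)) {
    v <- c(v, params$omega[, cc], log(params$alpha_ers[cc]),
           params$beta2[, cc], params$beta3[, cc])
  }
  if (estimate_corr) v <- c(v, atanh(params$latent_corr))
  v
}

unpack_params <- function(par, C, J, estimate_corr = TRUE, fixed_corr = 0) {
  i <- 0L
  take <- function(n) { out <- par[(i + 1L):(i + n)]; i <<- i + n; out }
  alpha_trait <- exp(take(J))
  beta1 <- take(J)
  if (C > 1) {
    s <- c(0, take(C - 1L))
    pi <- exp(s - max(s)); pi <- pi / sum(pi)
  } else pi <- 1
  omega <- matrix(0, J, C); alpha_ers <- numeric(C)
  beta2 <- matrix(0, J, C); beta3 <- matrix(0, J, C)
  for (cc in seq_len(C)) {
    omega[, cc] <- take(J)
    alpha_ers[cc] <- exp(take(1L))
    beta2[, cc] <- take(J)
    beta3[, cc] <- take(J)
  }
  corr <- if (estimate_corr) tanh(take(1L)) else fixed_corr
  mixtree_params(alpha_trait, beta1, omega, alpha_ers, beta2, beta3, pi, corr)
}

n_free <- function(C, J, estimate_corr = TRUE) {
  2L * J + (C - 1L) + C * (3L * J + 1L) + as.integer(estimate_corr)
}

pack_items <- function(params, estimate_corr = TRUE) {
  v <- c(log(params$alpha_trait), params$beta1)
  for (cc in seq_len(params$C)) {
    v <- c(v, params$omega[, cc], log(params$alpha_ers[cc]),
           params$beta2[, cc], params$beta3[, cc])
  }
  if (estimate_corr) v <- c(v, atanh(params$latent_corr))
  v
}

unpack_items <- function(par, C, J, pi, estimate_corr = TRUE, fixed_corr = 0) {
  i <- 0L
  take <- function(n) { out <- par[(i + 1L):(i + n)]; i <<- i + n; out }
  alpha_trait <- exp(take(J))
  beta1 <- take(J)
  omega <- matrix(0, J, C); alpha_ers <- numeric(C)
  beta2 <- matrix(0, J, C); beta3 <- matrix(0, J, C)
  for (cc in seq_len(C)) {
    omega[, cc] <- take(J)
    alpha_ers[cc] <- exp(take(1L))
    beta2[, cc] <- take(J)
    beta3[, cc] <- take(J)
  }
  corr <- if (estimate_corr) tanh(take(1L)) else fixed_corr
  mixtree_params(alpha_trait, beta1, omega, alpha_ers, beta2, beta3, pi, corr)
}

## Expected pseudo-item counts on the quadrature grid (Bock-Aitkin E-step):
## J x Q success/trial matrices per node, pooled over classes for the
## class-invariant direction node and per class for the extremity nodes.
expected_counts <- function(ind, R, C, Q) {
  Rtot <- 0
  per_class <- vector("list", C)
  for (cc in seq_len(C)) {
    Rc <- R[, ((cc - 1L) * Q + 1L):(cc * Q), drop = FALSE]
    Rtot <- Rtot + Rc
    per_class[[cc]] <- list(A2 = crossprod(ind$A2, Rc), V2 = crossprod(ind$V2, Rc),
                            A3 = crossprod(ind$A3, Rc), V3 = crossprod(ind$V3, Rc),
                            n = sum(Rc))
  }
  list(A1 = crossprod(ind$A1, Rtot), W1 = crossprod(ind$W1, Rtot),
       class = per_class)
}

## M-step objective: negative expected complete-data log-likelihood (item
## parameter part) with fixed expected counts, plus its analytic gradient.
## All quantities live in J x Q space, so inner iterations are cheap.
make_q_objective <- function(counts, C, J, grid0, estimate_corr = TRUE,
                             fixed_corr = 0) {
  Q <- length(grid0$w)
  ThetaM <- matrix(grid0$theta, J, Q, byrow = TRUE)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(invisible(NULL))
    params <- unpack_items(par, C, J, rep(1 / C, C), estimate_corr, fixed_corr)
    sigma <- params$latent_corr
    grid <- grid_set_corr(grid0, sigma)
    EtaM <- matrix(grid$eta, J, Q, byrow = TRUE)
    a <- params$alpha_trait
    val <- 0
    g_a <- numeric(J)
    g_class <- vector("list", C)
    g_sigma <- 0
    nm1 <- NULL
    E1 <- NULL
    for (cc in seq_len(C)) {
      nm <- node_matrices(params, grid, cc, want_p = TRUE)
      if (is.null(nm1)) {
        nm1 <- nm
        val <- val + sum(counts$A1 * nm$lp1 + (counts$W1 - counts$A1) * nm$lq1)
        E1 <- counts$A1 - counts$W1 * nm$P1
        g_a <- rowSums(E1 * ThetaM)
      }
      ct <- counts$class[[cc]]
      val <- val + sum(ct$A2 * nm$lp2 + (ct$V2 - ct$A2) * nm$lq2 +
                       ct$A3 * nm$lp3 + (ct$V3 - ct$A3) * nm$lq3)
      E2 <- ct$A2 - ct$V2 * nm$P2
      E3 <- ct$A3 - ct$V3 * nm$P3
      S23 <- rowSums((E2 + E3) * ThetaM)
      e <- params$alpha_ers[cc]
      g_class[[cc]] <- c(a * S23, e * sum((E3 - E2) * EtaM),
                         rowSums(E2), rowSums(E3))
      g_a <- g_a + params$omega[, cc] * S23
      if (estimate_corr)
        g_sigma <- g_sigma + e * sum(colSums(E3 - E2) *
                                     (grid$x1 - sigma / sqrt(1 - sigma^2) * grid$x2))
    }
    grad <- c(a * g_a, rowSums(E1), unlist(g_class))
    if (estimate_corr) grad <- c(grad, g_sigma * (1 - sigma^2))
    cache$par <- par
    cache$obj <- -val
    cache$grad <- -grad
    invisible(NULL)
  }
  list(fn = function(par) { evaluate(par); cache$obj },
       gr = function(par) { evaluate(par); cache$grad })
}

## Box constraints for the item-parameter vector (M-step scale).
item_bounds <- function(C, J, estimate_corr, omega_nonneg, bound_beta,
                        bound_loading) {
  np <- 2L * J + C * (3L * J + 1L) + as.integer(estimate_corr)
  lower <- rep(-bound_beta, np); upper <- rep(bound_beta, np)
  lower[seq_len(J)] <- log(0.05); upper[seq_len(J)] <- log(bound_loading)
  blk <- 3L * J + 1L
  for (cc in seq_len(C)) {
    iw <- 2L * J + (cc - 1L) * blk + seq_len(J)
    lower[iw] <- if (omega_nonneg) 0 else -bound_loading
    upper[iw] <- bound_loading
    ie <- 2L * J + (cc - 1L) * blk + J + 1L
    lower[ie] <- log(0.05); upper[ie] <- log(bound_loading)
  }
  if (estimate_corr) { lower[np] <- atanh(-0.95); upper[np] <- atanh(0.95) }
  list(lower = lower, upper = upper)
}

## EM estimation of one start: E-step via the joint (class, node) posterior,
## closed-form class-proportion update, quasi-Newton M-step on the expected
## counts.  The observed log-likelihood is monotone non-decreasing across
## cycles (up to M-step numerical tolerance); iteration stops when its
## relative change falls below `tol`.
em_run <- function(ind, C, J, grid0, start, estimate_corr, fixed_corr,
                   tol, max_cycles, bounds) {
  Q <- length(grid0$w)
  params <- start
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    grid <- grid_set_corr(grid0, params$latent_corr)
    marg <- mixture_marginal(ind, params, grid, posterior = TRUE)
    ll <- sum(marg$ll)
    trace <- c(trace, ll)
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
    ll_old <- ll
    counts <- expected_counts(ind, marg$R, C, Q)
    pi_new <- vapply(counts$class, `[[`, numeric(1), "n")
    pi_new <- pmax(pi_new / sum(pi_new), 1e-8); pi_new <- pi_new / sum(pi_new)
    qobj <- make_q_objective(counts, C, J, grid0, estimate_corr, fixed_corr)
    par0 <- pack_items(params, estimate_corr)
    # generalised EM: a capped quasi-Newton improvement of Q suffices for
    # monotone convergence and is much cheaper than solving the M-step fully
    res <- nlminb(par0, qobj$fn, qobj$gr, lower = bounds$lower,
                  upper = bounds$upper,
                  control = list(iter.max = 20L, rel.tol = 1e-9))
    params <- unpack_items(res$par, C, J, pi_new, estimate_corr, fixed_corr)
  }
  list(params = params, loglik = ll, converged = converged, trace = trace,
       cycles = length(trace))
}

## Objective factory: negative marginal log-likelihood and analytic gradient
## sharing one cached evaluation (nlminb queries fn and gr separately).
make_objective <- function(ind, C, J, quad_points, estimate_corr = TRUE,
                           fixed_corr = 0) {
  grid0 <- quadrature_grid(quad_points, 0)
  Q <- length(grid0$w)
  tA1 <- t(ind$A1); tW1 <- t(ind$W1)
  tA2 <- t(ind$A2); tV2 <- t(ind$V2)
  tA3 <- t(ind$A3); tV3 <- t(ind$V3)
  N <- ind$N
  ThetaM <- matrix(grid0$theta, J, Q, byrow = TRUE)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(invisible(NULL))
    params <- unpack_params(par, C, J, estimate_corr, fixed_corr)
    sigma <- params$latent_corr
    grid <- grid_set_corr(grid0, sigma)
    EtaM <- matrix(grid$eta, J, Q, byrow = TRUE)

    nms <- lapply(seq_len(C), function(cc) node_matrices(params, grid, cc, want_p = TRUE))
    L1 <- ind$A1 %*% nms[[1L]]$lp1 + ind$B1 %*% nms[[1L]]$lq1
    lw <- log(grid$w); lpi <- log(params$pi)
    NB <- do.call(cbind, lapply(seq_len(C), function(cc) {
      nm <- nms[[cc]]
      Lc <- L1 + ind$A2 %*% nm$lp2 + ind$B2 %*% nm$lq2 +
                 ind$A3 %*% nm$lp3 + ind$B3 %*% nm$lq3
      sweep(Lc, 2, lw, `+`) + lpi[cc]
    }))
    m <- NB[cbind(seq_len(N), max.col(NB, ties.method = "first"))]
    E <- exp(NB - m)
    S <- rowSums(E)
    ll <- sum(m + log(S))
    R <- E / S

    a <- params$alpha_trait
    g_la <- numeric(J); g_b1 <- numeric(J)
    g_s <- numeric(max(C - 1L, 0L))
    g_class <- vector("list", C)
    Rtot <- 0
    for (cc in seq_len(C)) Rtot <- Rtot + R[, ((cc - 1L) * Q + 1L):(cc * Q), drop = FALSE]
    E1 <- tA1 %*% Rtot - (tW1 %*% Rtot) * nms[[1L]]$P1
    g_b1 <- rowSums(E1)
    g_a <- rowSums(E1 * ThetaM)
    g_sigma <- 0
    for (cc in seq_len(C)) {
      Rc <- R[, ((cc - 1L) * Q + 1L):(cc * Q), drop = FALSE]
      nm <- nms[[cc]]
      E2 <- tA2 %*% Rc - (tV2 %*% Rc) * nm$P2
      E3 <- tA3 %*% Rc - (tV3 %*% Rc) * nm$P3
      S23 <- rowSums((E2 + E3) * ThetaM)
      e <- params$alpha_ers[cc]
      g_class[[cc]] <- c(a * S23,                       # omega
                         e * sum((E3 - E2) * EtaM),     # log alpha_ers
                         rowSums(E2),                   # beta2
                         rowSums(E3))                   # beta3
      g_a <- g_a + params$omega[, cc] * S23
      if (cc > 1L) g_s[cc - 1L] <- sum(Rc) - N * params$pi[cc]
      if (estimate_corr)
        g_sigma <- g_sigma + e * sum(colSums(E3 - E2) * (grid$x1 - sigma / sqrt(1 - sigma^2) * grid$x2))
    }
    grad <- c(a * g_a, g_b1, g_s, unlist(g_class))
    if (estimate_corr) grad <- c(grad, g_sigma * (1 - sigma^2))

    cache$par <- par
    cache$obj <- -ll
    cache$grad <- -grad
    invisible(NULL)
  }

  list(
    fn = function(par) { evaluate(par); cache$obj },
    gr = function(par) { evaluate(par); cache$grad }
  )
}
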