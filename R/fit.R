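#' Fit a mixture IRTree model
#'
#' Estimates the class proportions and all item parameters of a C-class
#' mixture IRTree for four-point items by marginal maximum likelihood
#' (step 1 of the three-step procedure), then computes posterior class
#' membership probabilities, modal assignments, the classification-error
#' matrix and EAP trait/ERS scores (step 2).  The latent pair is integrated
#' out over a Gauss-Hermite product grid; the marginal log-likelihood is
#' maximised by an EM algorithm of the Bock-Aitkin type (expected
#' pseudo-item counts on the grid in the E-step, bounded quasi-Newton
#' logistic fits with analytic gradients in the M-step, closed-form class
#' proportions), from several random starts that perturb a single-class
#' warm-start solution.  The best
#' converged start by log-likelihood is retained and classes are relabelled
#' into the canonical order of descending ERS loading (satisficing-like
#' strategies first).
#'
#' @param responses N x J matrix/data frame with entries in \{1,2,3,4\}
#'   (`NA` allowed, treated as missing at random).
#' @param classes number of latent classes C.
#' @param n_starts number of random starts; defaults to 4 for one class and
#'   8 otherwise.
#' @param quad_points quadrature nodes per latent dimension (default 15).
#' @param latent_corr `NULL` to estimate the trait-ERS correlation (default)
#'   or a fixed value in (-1, 1).
#' @param omega_nonneg constrain the proportionality constants to be
#'   non-negative.
#' @param tol relative log-likelihood-change convergence tolerance of the EM.
#' @param max_iter maximum EM cycles per start.
#' @param seed optional integer seed controlling the random starts.
#' @param start_sd perturbation scale of the random starts.
#' @param bounds named vector with elements `beta` (box on all intercepts)
#'   and `loading` (upper bound on trait/ERS loadings and `|omega|`).  The
#'   defaults cover the plausible parameter space of four-point rating items
#'   with wide margin and keep mixture ML away from degenerate spurious
#'   components.
#' @param verbose print per-start progress.
#' @return An object of class `"mixtree"`: a list with components `params`
#'   ([mixtree_params()]), `loglik`, `start_logliks`, `converged`, `trace`
#'   (running-best objective per start), `posterior` (N x C), `assignment`,
#'   `error_matrix`, `total_error`, `eap` (data frame with `theta`, `eta`,
#'   `se_theta`, `se_eta`), `npar`, and the call.
#' @examples
#' \donttest{
#' sim <- sim_mixtree_data(N = 300, J = 10, C = 1, seed = 1)
#' fit <- mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 7)
#' fit
#' }
#' @export
mixtree <- function(responses, classes = 1L, n_starts = NULL,
                    quad_points = 15L, latent_corr = NULL,
                    omega_nonneg = FALSE, tol = 1e-6, max_iter = 500L,
                    seed = NULL, start_sd = 0.4,
                    bounds = c(beta = 5, loading = 3), verbose = FALSE) {
  cl <- match.call()
  pseudo <- if (inherits(responses, "pseudo_items")) responses else pseudo_items(responses)
  ind <- pseudo_indicators(pseudo)
  C <- as.integer(classes); J <- ind$J; N <- ind$N
  if (C < 1L) stop("classes must be >= 1")
  if (N < 200L) warning("fewer than 200 respondents; mixture estimates may be unstable")
  if (is.null(n_starts)) n_starts <- if (C == 1L) 4L else 8L
  estimate_corr <- is.null(latent_corr)
  fixed_corr <- if (estimate_corr) 0 else latent_corr

  runs <- with_seed(seed, {
    warm <- fit_single_class(ind, quad_points, estimate_corr, fixed_corr,
                             tol, max_iter)
    optimise_starts(ind, C, J, quad_points, estimate_corr, fixed_corr,
                    tol, max_iter, omega_nonneg, n_starts, warm, start_sd,
                    verbose, bound_beta = bounds[["beta"]],
                    bound_loading = bounds[["loading"]])
  })

  logliks <- vapply(runs, function(r) r$loglik, numeric(1))
  conv <- vapply(runs, function(r) r$converged, logical(1))
  if (!any(is.finite(logliks))) {
    cond <- structure(class = c("mixtree_nonconvergence", "error", "condition"),
                      list(message = "all starts failed to produce a finite log-likelihood",
                           call = cl, diagnostics = runs))
    stop(cond)
  }
  use <- if (any(conv)) which(conv) else seq_along(runs)
  if (!any(conv))
    warning("no start reached the convergence tolerance; returning the best available solution")
  best <- use[which.max(logliks[use])]
  params <- runs[[best]]$params
  ord <- order(params$alpha_ers, decreasing = TRUE)
  params <- permute_classes(params, ord)

  grid <- quadrature_grid(quad_points, params$latent_corr)
  post <- mixture_marginal(ind, params, grid, posterior = TRUE)
  lat <- latent_summary(post, grid, C)
  assignment <- modal_assign(lat$class_post)
  pi_hat <- colMeans(lat$class_post)
  err <- classification_error(lat$class_post, assignment, pi_hat)

  structure(list(call = cl, params = params, loglik = sum(post$ll),
                 person_loglik = post$ll,
                 n_starts = n_starts, start_logliks = logliks,
                 start_convergence = conv, converged = any(conv),
                 trace = runs[[best]]$trace,
                 posterior = lat$class_post, assignment = assignment,
                 error_matrix = err$D, total_error = err$total_error,
                 eap = lat$eap, N = N, J = J, C = C,
                 quad_points = quad_points,
                 estimate_corr = estimate_corr,
                 npar = n_free(C, J, estimate_corr),
                 counts = count_parameters(C, J)),
            class = "mixtree")
}

## Posterior class probabilities and EAP scores from the joint (class, node)
## posterior weight matrix.
latent_summary <- function(post, grid, C) {
  Q <- post$Q
  R <- post$R
  N <- nrow(R)
  class_post <- matrix(0, N, C)
  Rtot <- 0
  for (cc in seq_len(C)) {
    Rc <- R[, ((cc - 1L) * Q + 1L):(cc * Q), drop = FALSE]
    class_post[, cc] <- rowSums(Rc)
    Rtot <- Rtot + Rc
  }
  th <- as.vector(Rtot %*% grid$theta)
  th2 <- as.vector(Rtot %*% grid$theta^2)
  et <- as.vector(Rtot %*% grid$eta)
  et2 <- as.vector(Rtot %*% grid$eta^2)
  eap <- data.frame(theta = th, se_theta = sqrt(pmax(th2 - th^2, 0)),
                    eta = et, se_eta = sqrt(pmax(et2 - et^2, 0)))
  list(class_post = class_post, eap = eap)
}

permute_classes <- function(params, ord) {
  mixtree_params(params$alpha_trait, params$beta1,
                 params$omega[, ord, drop = FALSE],
                 params$alpha_ers[ord],
                 params$beta2[, ord, drop = FALSE],
                 params$beta3[, ord, drop = FALSE],
                 params$pi[ord], params$latent_corr)
}

## Frequency-based deterministic starting values for one class.
start_single <- function(ind) {
  clamp <- function(p) pmin(pmax(p, 0.05), 0.95)
  p1 <- clamp(colSums(ind$A1) / pmax(colSums(ind$W1), 1))
  p2 <- clamp(colSums(ind$A2) / pmax(colSums(ind$V2), 1))
  p3 <- clamp(colSums(ind$A3) / pmax(colSums(ind$V3), 1))
  J <- ind$J
  mixtree_params(alpha_trait = rep(1, J), beta1 = qlogis(p1),
                 omega = matrix(0.6, J, 1), alpha_ers = 0.6,
                 beta2 = matrix(qlogis(p2), J, 1),
                 beta3 = matrix(qlogis(p3), J, 1), pi = 1, latent_corr = 0)
}

fit_single_class <- function(ind, quad_points, estimate_corr, fixed_corr,
                             tol, max_iter) {
  grid0 <- quadrature_grid(quad_points, 0)
  bnd <- item_bounds(1L, ind$J, estimate_corr, FALSE, 5, 3)
  em_run(ind, 1L, ind$J, grid0, start_single(ind), estimate_corr, fixed_corr,
         tol, max_iter, bnd)$params
}

## Expand a single-class solution into a C-class start with random jitter.
perturb_start <- function(warm, C, sd, first = FALSE) {
  J <- warm$J
  s <- if (first) sd / 2 else sd
  omega <- matrix(warm$omega[, 1], J, C) + matrix(runif(J * C, -s, s), J, C)
  alpha_ers <- pmax(warm$alpha_ers[1] * exp(rnorm(C, 0, s)), 0.05)
  beta2 <- matrix(warm$beta2[, 1], J, C) + matrix(rnorm(J * C, 0, s), J, C)
  beta3 <- matrix(warm$beta3[, 1], J, C) + matrix(rnorm(J * C, 0, s), J, C)
  pi <- exp(rnorm(C, 0, 0.2)); pi <- pi / sum(pi)
  at <- pmax(warm$alpha_trait * exp(rnorm(J, 0, s / 2)), 0.05)
  mixtree_params(at, warm$beta1 + rnorm(J, 0, s / 2), omega, alpha_ers,
                 beta2, beta3, pi, warm$latent_corr)
}

optimise_starts <- function(ind, C, J, quad_points, estimate_corr, fixed_corr,
                            tol, max_iter, omega_nonneg, n_starts, warm,
                            start_sd, verbose, bound_beta = 5,
                            bound_loading = 3) {
  # The M-step operates under stabilising boxes covering the plausible
  # parameter space of four-point rating items with ample margin:
  # intercepts in [-5, 5], loadings in (0.05, 3], |omega| <= 3,
  # |corr| <= 0.95.  They keep small spurious classes from drifting to
  # near-deterministic node probabilities (the classic degenerate-component
  # pathology of mixture likelihoods).
  grid0 <- quadrature_grid(quad_points, 0)
  bnd <- item_bounds(C, J, estimate_corr, omega_nonneg, bound_beta,
                     bound_loading)
  lapply(seq_len(n_starts), function(k) {
    start <- if (C == 1L && k == 1L) warm
             else perturb_start(warm, C, start_sd, first = C > 1L && k == 1L)
    res <- tryCatch(
      em_run(ind, C, J, grid0, start, estimate_corr, fixed_corr, tol,
             max_iter, bnd),
      error = function(e) NULL)
    if (is.null(res)) {
      if (verbose) message(sprintf("start %d: failed", k))
      return(list(loglik = -Inf, converged = FALSE, params = start,
                  trace = numeric(0), message = "EM error"))
    }
    if (verbose)
      message(sprintf("start %d: logLik %.3f after %d EM cycles", k,
                      res$loglik, res$cycles))
    list(loglik = res$loglik, converged = res$converged, params = res$params,
         trace = res$trace, message = sprintf("%d EM cycles", res$cycles))
  })
}

#' @export
print.mixtree <- function(x, ...) {
  cat(sprintf("MixTree-%d fit: %d persons, %d items\n", x$C, x$N, x$J))
  cat(sprintf("  logLik %.3f (%d free parameters, %d starts, converged: %s)\n",
              x$loglik, x$npar, x$n_starts, x$converged))
  cat("  class proportions:", paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  if (x$C > 1)
    cat(sprintf("  R2 entropy %.3f, mean classification accuracy %.3f\n",
                r2_entropy(x$posterior), mean(diag(x$error_matrix))))
  invisible(x)
}

#' @export
summary.mixtree <- function(object, ...) {
  p <- object$params
  ic <- information_criteria(object)
  cls <- data.frame(class = seq_len(object$C),
                    pi = p$pi,
                    alpha_ers = p$alpha_ers,
                    mean_omega = colMeans(p$omega),
                    mean_trait_loading = colMeans(p$omega * p$alpha_trait),
                    accuracy = diag(object$error_matrix))
  out <- list(C = object$C, N = object$N, J = object$J,
              loglik = object$loglik, ic = ic, classes = cls,
              latent_corr = p$latent_corr,
              r2_entropy = if (object$C > 1) r2_entropy(object$posterior) else NA_real_,
              total_error = object$total_error,
              item_params = data.frame(item = seq_len(object$J),
                                       alpha_trait = p$alpha_trait,
                                       beta1 = p$beta1))
  class(out) <- "summary.mixtree"
  out
}

#' @export
print.summary.mixtree <- function(x, ...) {
  cat(sprintf("MixTree-%d (%d persons, %d items)\n", x$C, x$N, x$J))
  cat(sprintf("  logLik %.3f | AIC %.1f | BIC %.1f | HBIC %.1f\n",
              x$loglik, x$ic["aic"], x$ic["bic"], x$ic["hbic"]))
  cat(sprintf("  trait-ERS correlation: %.3f\n", x$latent_corr))
  if (x$C > 1)
    cat(sprintf("  R2 entropy %.3f | total classification error %.3f\n",
                x$r2_entropy, x$total_error))
  cat("\nClass summary (canonical order: descending ERS loading):\n")
  print(x$classes, row.names = FALSE, digits = 3)
  cat("\nDirection-node item parameters (first items):\n")
  print(head(x$item_params, 6), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.mixtree <- function(object, ...) object$params

#' @export
logLik.mixtree <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$N,
            class = "logLik")
}

#' Predict from a fitted MixTree model
#'
#' @param object a `"mixtree"` fit.
#' @param newdata optional response matrix; defaults to the training data
#'   quantities stored in the fit.
#' @param type `"posterior"` (class membership probabilities), `"class"`
#'   (modal assignment), or `"eap"` (trait/ERS scores with posterior SDs).
#' @param ... unused.
#' @export
predict.mixtree <- function(object, newdata = NULL,
                            type = c("posterior", "class", "eap"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type,
                  posterior = object$posterior,
                  class = object$assignment,
                  eap = object$eap))
  }
  pseudo <- if (inherits(newdata, "pseudo_items")) newdata else pseudo_items(newdata)
  ind <- pseudo_indicators(pseudo)
  grid <- quadrature_grid(object$quad_points, object$params$latent_corr)
  post <- mixture_marginal(ind, object$params, grid, posterior = TRUE)
  lat <- latent_summary(post, grid, object$C)
  switch(type,
         posterior = lat$class_post,
         class = modal_assign(lat$class_post),
         eap = lat$eap)
}

#' Simulate response data from a fitted MixTree model
#'
#' Draws class memberships from the estimated proportions, latent scores
#' from the (correlated) standard bivariate normal, and responses from the
#' category probabilities.
#'
#' @param object a `"mixtree"` fit.
#' @param nsim number of data sets.
#' @param seed optional integer seed.
#' @param N number of respondents per data set (defaults to the fitted N).
#' @param ... unused.
#' @return A list of `nsim` response matrices with attributes `"class"`,
#'   `"theta"`, `"eta"`.
#' @export
simulate.mixtree <- function(object, nsim = 1, seed = NULL, N = NULL, ...) {
  if (is.null(N)) N <- object$N
  p <- object$params
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    cls <- sample.int(p$C, N, replace = TRUE, prob = p$pi)
    sc <- sample_latent_scores(N, p$latent_corr)
    y <- generate_responses(p, cls, sc)
    attr(y, "class_membership") <- cls
    attr(y, "theta") <- sc$theta
    attr(y, "eta") <- sc$eta
    y
  }))
}

#' Plot class-specific extremity-node probabilities
#'
#' Draws, for each class, the probability of the extreme-agreement decision
#' as a function of the trait for several ERS levels — the visual signature
#' of satisficing- versus optimizing-dominated response strategies.
#'
#' @param x a `"mixtree"` fit.
#' @param item item index used for the curves.
#' @param eta_levels ERS values at which to draw the curves.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mixtree <- function(x, item = 1L, eta_levels = c(-1.5, 0, 1.5), ...) {
  theta <- seq(-3, 3, length.out = 101)
  op <- graphics::par(mfrow = c(1, x$C), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cc in seq_len(x$C)) {
    p3 <- sapply(eta_levels, function(e)
      node_probabilities(x$params, theta, e, item, cc)[, "p3"])
    graphics::matplot(theta, p3, type = "l", lty = seq_along(eta_levels),
                      col = 1, ylim = c(0, 1),
                      xlab = expression(theta), ylab = "P(extreme agreement)",
                      main = sprintf("class %d (ERS loading %.2f)", cc,
                                     x$params$alpha_ers[cc]), ...)
    graphics::legend("topleft", bty = "n", lty = seq_along(eta_levels),
                     legend = sprintf("eta = %.1f", eta_levels), cex = 0.8)
  }
  invisible(x)
}
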