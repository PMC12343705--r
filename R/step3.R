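#' Classification-error-corrected covariate regression (step 3)
#'
#' Regresses latent class membership on covariates while correcting for the
#' error in the modal assignments.  The model treats the assigned class
#' `w_p` as the sole indicator of the true class `X`, with the
#' classification-error matrix `D` (`D[c, k] = P(w = k | X = c)`) held fixed
#' at its step-2 estimate and `P(X = c | Z_p)` following a multinomial
#' logistic regression (reference class 1).  Estimation is an EM over the
#' true-class indicator with a Newton weighted multinomial-logit M-step;
#' with `D` the identity the procedure reduces exactly to an ordinary
#' multinomial logistic regression of `w` on `Z`.  Standard errors come from
#' the observed information of the step-3 likelihood and ignore step-1
#' sampling error.
#'
#' @param assignment length-N class assignments, or a `"mixtree"` fit (whose
#'   assignments and error matrix are used).
#' @param covariates N x T numeric covariate matrix or data frame.
#' @param error C x C row-stochastic classification-error matrix; identity
#'   if omitted (no correction).
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return An object of class `"mixtree_covmod"`: coefficients `gamma`
#'   ((T+1) x C, reference column fixed at 0), matching `se`, `loglik`,
#'   `vcov`, and the inputs.
#' @export
mixtree_covariates <- function(assignment, covariates, error = NULL,
                               tol = 1e-10, max_iter = 500L) {
  if (inherits(assignment, "mixtree")) {
    fit <- assignment
    if (is.null(error)) error <- fit$error_matrix
    assignment <- fit$assignment
  }
  w <- as.integer(assignment)
  Z <- as.matrix(covariates)
  if (!is.numeric(Z)) stop("covariates must be numeric")
  N <- length(w)
  stopifnot(nrow(Z) == N)
  C <- max(w, if (!is.null(error)) nrow(error) else 0L)
  if (C < 2L) stop("covariate effects require at least two classes")
  if (is.null(error)) error <- diag(C)
  error <- as.matrix(error)
  stopifnot(nrow(error) == C, ncol(error) == C)
  if (any(abs(rowSums(error) - 1) > 1e-6))
    stop("classification-error matrix must be row-stochastic")
  X <- cbind(`(Intercept)` = 1, Z)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is singular")
  Tn <- ncol(X)
  if (is.null(colnames(Z))) colnames(X)[-1L] <- paste0("z", seq_len(Tn - 1L))

  Dw <- t(error)[w, , drop = FALSE]    # N x C: D[c, w_p] per row
  obs_ll <- function(B) {
    P <- softmax_rows(X %*% cbind(0, B))
    sum(log(pmax(rowSums(P * Dw), 1e-300)))
  }

  B <- matrix(0, Tn, C - 1L)
  ll <- obs_ll(B)
  for (it in seq_len(max_iter)) {
    P <- softmax_rows(X %*% cbind(0, B))
    Q <- P * Dw
    Q <- Q / rowSums(Q)               # E-step: P(X = c | w_p, Z_p)
    B <- multilogit_newton(X, Q, B)   # M-step
    ll_new <- obs_ll(B)
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }
  if (any(abs(B) > 15))
    warning("very large coefficients detected: possible (quasi-)separation, estimates may be unbounded")

  theta <- as.vector(B)
  H <- pracma::hessian(function(th) obs_ll(matrix(th, Tn, C - 1L)), theta)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  se <- matrix(sqrt(pmax(diag(V), 0)), Tn, C - 1L)

  gamma <- cbind(0, B)
  se_full <- cbind(0, se)
  dimnames(gamma) <- dimnames(se_full) <-
    list(colnames(X), paste0("class", seq_len(C)))
  structure(list(gamma = gamma, se = se_full, loglik = ll, vcov = V,
                 error = error, C = C, N = N, T = Tn - 1L,
                 assignment = w, iterations = it),
            class = "mixtree_covmod")
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

## One full Newton solve of the weighted multinomial logit
## max_B sum_p sum_c Q[p,c] log P_c(x_p; B), reference class 1.
multilogit_newton <- function(X, Q, B, tol = 1e-10, max_iter = 50L) {
  Tn <- ncol(X); C <- ncol(Q)
  np <- Tn * (C - 1L)
  wll <- function(B) sum(Q * log(pmax(softmax_rows(X %*% cbind(0, B)), 1e-300)))
  ll <- wll(B)
  for (it in seq_len(max_iter)) {
    P <- softmax_rows(X %*% cbind(0, B))
    G <- crossprod(X, Q[, -1L, drop = FALSE] - P[, -1L, drop = FALSE])
    H <- matrix(0, np, np)
    for (a in 2:C) for (b in 2:C) {
      wab <- P[, a] * ((a == b) - P[, b])
      blk <- crossprod(X, X * wab)
      ia <- (a - 2L) * Tn + seq_len(Tn)
      ib <- (b - 2L) * Tn + seq_len(Tn)
      H[ia, ib] <- blk
    }
    step <- tryCatch(solve(H + diag(1e-10, np), as.vector(G)),
                     error = function(e) as.vector(G) * 1e-3)
    damp <- 1
    repeat {
      Bn <- B + matrix(damp * step, Tn, C - 1L)
      lln <- wll(Bn)
      if (lln >= ll - 1e-12 || damp < 1e-6) break
      damp <- damp / 2
    }
    moved <- abs(lln - ll)
    B <- Bn; ll <- lln
    if (moved < tol * (abs(ll) + 1)) break
  }
  B
}

#' @export
print.mixtree_covmod <- function(x, ...) {
  cat(sprintf("Corrected covariate model: %d classes, %d covariates, N = %d\n",
              x$C, x$T, x$N))
  cat(sprintf("  logLik %.3f (EM iterations: %d)\n", x$loglik, x$iterations))
  cat("\nCoefficients (reference: class 1):\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' @export
summary.mixtree_covmod <- function(object, ...) {
  est <- object$gamma[, -1L, drop = FALSE]
  se <- object$se[, -1L, drop = FALSE]
  z <- est / se
  tab <- data.frame(class = rep(colnames(est), each = nrow(est)),
                    term = rep(rownames(est), ncol(est)),
                    estimate = as.vector(est), se = as.vector(se),
                    z = as.vector(z),
                    p = 2 * pnorm(-abs(as.vector(z))))
  out <- list(table = tab, loglik = object$loglik, C = object$C, N = object$N)
  class(out) <- "summary.mixtree_covmod"
  out
}

#' @export
print.summary.mixtree_covmod <- function(x, ...) {
  cat(sprintf("Corrected covariate model (C = %d, N = %d, logLik %.3f)\n\n",
              x$C, x$N, x$loglik))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mixtree_covmod <- function(object, ...) object$gamma

#' @export
logLik.mixtree_covmod <- function(object, ...) {
  structure(object$loglik, df = (object$T + 1L) * (object$C - 1L),
            nobs = object$N, class = "logLik")
}

#' Class membership probabilities from covariates
#'
#' Evaluates the multinomial logistic model `P(X = c | z) =
#' exp(g0c + sum_t gtc z_t) / sum_c' exp(...)` with the reference class
#' anchored at 0.
#'
#' @param object a `"mixtree_covmod"` fit or a (T+1) x C coefficient matrix
#'   (intercept row first, reference column zero).
#' @param newdata covariate matrix/vector (without intercept column).
#' @param ... unused.
#' @return Matrix of class probabilities, one row per covariate row.
#' @export
predict.mixtree_covmod <- function(object, newdata, ...) {
  gamma <- if (inherits(object, "mixtree_covmod")) object$gamma else as.matrix(object)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Z <- as.matrix(newdata)
  stopifnot(ncol(Z) == nrow(gamma) - 1L)
  softmax_rows(cbind(1, Z) %*% gamma)
}

#' @rdname predict.mixtree_covmod
#' @export
predict_class_probs <- function(object, newdata, ...) {
  predict.mixtree_covmod(object, newdata, ...)
}
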