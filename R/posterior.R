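#' Posterior class membership probabilities
#'
#' Bayes-rule posteriors: row p is proportional to the estimated class
#' proportion times the class-conditional marginal likelihood of person p's
#' responses.
#'
#' @param fit a `"mixtree"` fit.
#' @param responses optional response matrix; defaults to the stored
#'   training posteriors.
#' @return N x C matrix with rows summing to 1.
#' @export
posterior_class_probs <- function(fit, responses = NULL) {
  stopifnot(inherits(fit, "mixtree"))
  if (is.null(responses)) return(fit$posterior)
  predict(fit, newdata = responses, type = "posterior")
}

#' EAP trait and ERS scores
#'
#' Expected a posteriori latent scores, marginalised over classes and
#' quadrature nodes, with posterior SDs as standard errors.
#'
#' @inheritParams posterior_class_probs
#' @return Data frame with columns `theta`, `se_theta`, `eta`, `se_eta`.
#' @export
eap_scores <- function(fit, responses = NULL) {
  stopifnot(inherits(fit, "mixtree"))
  if (is.null(responses)) return(fit$eap)
  predict(fit, newdata = responses, type = "eap")
}

#' Modal class assignment
#'
#' Assigns each respondent to the class with the largest posterior
#' membership probability.  Exact ties are broken toward the lowest class
#' index and reported through the `"ties"` attribute.
#'
#' @param posterior N x C matrix of posterior probabilities.
#' @return Integer vector of class indices with attribute `"ties"` (rows at
#'   which a tie was broken).
#' @export
modal_assign <- function(posterior) {
  posterior <- as.matrix(posterior)
  w <- max.col(posterior, ties.method = "first")
  rowmax <- posterior[cbind(seq_len(nrow(posterior)), w)]
  nmax <- rowSums(abs(posterior - rowmax) < 1e-12)
  ties <- which(nmax > 1L)
  if (length(ties))
    attr(w, "ties") <- ties
  w
}

#' Classification-error matrix
#'
#' The C x C matrix `D` with `D[c, k] = P(w = k | X = c)`: the probability
#' that a respondent whose true class is c is assigned to class k, estimated
#' by averaging posterior probabilities over the modal assignments,
#'
#' `D[c, k] = (1/N) sum_p post[p, c] * 1(w_p = k) / P(X = c)`.
#'
#' The total error is `sum_c P(X = c) sum_{k != c} D[c, k]`.
#'
#' @param posterior N x C posterior probability matrix.
#' @param assignment length-N modal assignments.
#' @param pi length-C unconditional class proportions `P(X = c)` (typically
#'   the mean posterior).
#' @return List with the row-stochastic matrix `D` and `total_error`.
#' @export
classification_error <- function(posterior, assignment, pi) {
  posterior <- as.matrix(posterior)
  C <- ncol(posterior)
  N <- nrow(posterior)
  stopifnot(length(assignment) == N, length(pi) == C)
  if (any(pi <= 0))
    stop(sprintf("class %d has zero estimated probability; classification errors are undefined",
                 which(pi <= 0)[1L]))
  D <- matrix(0, C, C)
  for (k in seq_len(C)) {
    sel <- assignment == k
    D[, k] <- colSums(posterior[sel, , drop = FALSE]) / (N * pi)
  }
  D <- D / rowSums(D)   # guard tiny numerical drift; exact when pi = colMeans
  total_error <- sum(pi * (rowSums(D) - diag(D)))
  list(D = D, total_error = total_error)
}
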