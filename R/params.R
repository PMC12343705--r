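#' Construct a MixTree parameter set
#'
#' Bundles all parameters of a C-class mixture IRTree for J four-point items.
#' The direction node is class-invariant with trait loadings `alpha_trait`
#' and intercepts `beta1`.  The extremity nodes are class-specific: the trait
#' enters through `alpha_trait[j] * omega[j, c]` (the proportionality
#' constant scales the trait's role at the extremity nodes relative to the
#' direction node), the ERS factor through the item-invariant loading
#' `alpha_ers[c]` (negative sign at the disagreement-extremity node, positive
#' at the agreement-extremity node), with intercepts `beta2` / `beta3`.
#' Both latent variables have mean 0 and variance 1 in every class
#' (identification); `latent_corr` is their class-invariant correlation.
#'
#' @param alpha_trait length-J positive trait loadings (direction node).
#' @param beta1 length-J direction-node intercepts.
#' @param omega J x C matrix of trait proportionality constants.
#' @param alpha_ers length-C ERS loadings.
#' @param beta2 J x C disagreement-extremity intercepts.
#' @param beta3 J x C agreement-extremity intercepts.
#' @param pi length-C class proportions (positive, summing to 1).
#' @param latent_corr trait-ERS correlation in (-1, 1).
#' @return An object of class `"mixtree_params"`.
#' @export
mixtree_params <- function(alpha_trait, beta1, omega, alpha_ers, beta2, beta3,
                           pi = 1, latent_corr = 0) {
  J <- length(alpha_trait)
  omega <- as.matrix(omega); beta2 <- as.matrix(beta2); beta3 <- as.matrix(beta3)
  C <- length(alpha_ers)
  stopifnot(length(beta1) == J,
            nrow(omega) == J, ncol(omega) == C,
            nrow(beta2) == J, ncol(beta2) == C,
            nrow(beta3) == J, ncol(beta3) == C,
            length(pi) == C)
  if (any(alpha_trait <= 0)) stop("alpha_trait must be positive")
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) stop("pi must be a positive simplex")
  if (abs(latent_corr) >= 1) stop("latent_corr must lie in (-1, 1)")
  structure(list(alpha_trait = as.numeric(alpha_trait),
                 beta1 = as.numeric(beta1),
                 omega = omega, alpha_ers = as.numeric(alpha_ers),
                 beta2 = beta2, beta3 = beta3,
                 pi = as.numeric(pi) / sum(pi),
                 latent_corr = as.numeric(latent_corr),
                 J = J, C = C),
            class = "mixtree_params")
}

#' @export
print.mixtree_params <- function(x, ...) {
  cat(sprintf("MixTree parameters: %d items, %d class%s, trait-ERS corr %.3f\n",
              x$J, x$C, if (x$C > 1) "es" else "", x$latent_corr))
  cat("  class proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("  ERS loadings:     ", paste(sprintf("%.3f", x$alpha_ers), collapse = " "), "\n")
  invisible(x)
}

#' Node endorsement probabilities
#'
#' Probability of endorsing each tree node (direction, disagreement
#' extremity, agreement extremity) for given latent scores, one item, and
#' one class.  The linear predictors are
#' `alpha_trait * theta + beta1`,
#' `alpha_trait * omega * theta - alpha_ers * eta + beta2`, and
#' `alpha_trait * omega * theta + alpha_ers * eta + beta3`,
#' each passed through the inverse logit.
#'
#' @param params a [mixtree_params()] object.
#' @param theta,eta numeric latent trait / ERS scores (vectorised).
#' @param item item index (1-based).
#' @param class_id class index (1-based).
#' @return Matrix with columns `p1`, `p2`, `p3` (rows follow `theta`).
#' @export
node_probabilities <- function(params, theta, eta, item, class_id = 1L) {
  stopifnot(inherits(params, "mixtree_params"),
            item >= 1L, item <= params$J,
            class_id >= 1L, class_id <= params$C)
  a <- params$alpha_trait[item]
  w <- params$omega[item, class_id]
  e <- params$alpha_ers[class_id]
  p1 <- plogis(a * theta + params$beta1[item])
  p2 <- plogis(a * w * theta - e * eta + params$beta2[item, class_id])
  p3 <- plogis(a * w * theta + e * eta + params$beta3[item, class_id])
  cbind(p1 = p1, p2 = p2, p3 = p3)
}

#' Category probabilities under the response tree
#'
#' Composes the node probabilities into the four category probabilities:
#' `P(1) = (1-p1)(1-p2)`, `P(2) = (1-p1)p2`, `P(3) = p1(1-p3)`,
#' `P(4) = p1 p3`.
#'
#' @inheritParams node_probabilities
#' @return Matrix with columns `"1"` to `"4"`, rows following `theta`.
#' @export
category_probabilities <- function(params, theta, eta, item, class_id = 1L) {
  p <- node_probabilities(params, theta, eta, item, class_id)
  out <- cbind((1 - p[, 1]) * (1 - p[, 2]),
               (1 - p[, 1]) * p[, 2],
               p[, 1] * (1 - p[, 3]),
               p[, 1] * p[, 3])
  colnames(out) <- as.character(1:4)
  out
}

#' Free-parameter counts of a C-class MixTree
#'
#' The class-invariant block has `2J` direction-node parameters, the latent
#' correlation, and `C - 1` mixing proportions: `n_k0 = 2J + 1 + (C - 1)`.
#' Each class contributes `3J + 1` class-specific parameters (`omega`,
#' `beta2`, `beta3` per item plus the ERS loading): `n_kc = C (3J + 1)`.
#'
#' @param C number of classes (>= 1).
#' @param J number of items (>= 1).
#' @return Named numeric vector `c(n_k, n_k0, n_kc)` with
#'   `n_k = n_k0 + n_kc`.
#' @examples
#' count_parameters(2, 20)  # n_k = 164
#' @export
count_parameters <- function(C, J) {
  if (length(C) != 1L || length(J) != 1L || is.na(C) || is.na(J) ||
      C < 1 || J < 1 || C != round(C) || J != round(J))
    stop("C and J must be positive integers")
  n_k0 <- 2 * J + 1 + (C - 1)
  n_kc <- C * (3 * J + 1)
  c(n_k = n_k0 + n_kc, n_k0 = n_k0, n_kc = n_kc)
}
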