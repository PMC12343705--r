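#' Align class labels between two parameter sets
#'
#' Mixture likelihoods are invariant to permutations of the class labels, so
#' labels from independent fits (random starts, simulation truth vs.
#' estimate, train vs. test folds) need not agree.  This finds the
#' permutation of the candidate's classes minimising the total squared
#' distance between the class-specific parameter blocks (`omega`,
#' `alpha_ers`, `beta2`, `beta3`) and the reference, over all C!
#' permutations.
#'
#' @param reference,candidate [mixtree_params()] objects with equal C and J.
#' @return The relabelled candidate with attribute `"permutation"` (the
#'   column order applied) and `"distance"`.
#' @export
align_labels <- function(reference, candidate) {
  stopifnot(inherits(reference, "mixtree_params"),
            inherits(candidate, "mixtree_params"),
            reference$C == candidate$C, reference$J == candidate$J)
  C <- reference$C
  perms <- permutations(C)
  block <- function(p, ord) {
    c(p$omega[, ord, drop = FALSE], p$alpha_ers[ord],
      p$beta2[, ord, drop = FALSE], p$beta3[, ord, drop = FALSE])
  }
  ref <- block(reference, seq_len(C))
  d <- vapply(seq_len(nrow(perms)), function(i)
    sum((block(candidate, perms[i, ]) - ref)^2), numeric(1))
  best <- as.integer(perms[which.min(d), ])
  out <- permute_classes(candidate, best)
  attr(out, "permutation") <- best
  attr(out, "distance") <- min(d)
  out
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
  dimnames(out) <- NULL
  out
}
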