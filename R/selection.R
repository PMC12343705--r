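#' Information criteria with MixTree parameter-count bookkeeping
#'
#' Computes `AIC = -2 logL + 2 n_k`, `BIC = -2 logL + log(N) n_k` and the
#' hierarchical `HBIC = -2 logL + n_k0 log(N) + sum_c (3J + 1) log(pi_c N)`,
#' where the parameter counts come from [count_parameters()]: `n_k0`
#' class-invariant parameters pay the full `log N` penalty while each
#' class-specific block pays `log(pi_c N)`, the effective sample size of its
#' class.  With one class HBIC equals BIC.
#'
#' @param loglik maximised step-1 log-likelihood, or a `"mixtree"` fit (in
#'   which case the remaining arguments are taken from the fit).
#' @param C,J,N classes, items, respondents.
#' @param pi length-C class proportions (HBIC only).
#' @return Named vector `c(aic, bic, hbic)`.
#' @export
information_criteria <- function(loglik, C, J, N, pi = NULL) {
  if (inherits(loglik, "mixtree")) {
    fit <- loglik
    return(information_criteria(fit$loglik, fit$C, fit$J, fit$N, fit$params$pi))
  }
  stopifnot(N > 0)
  cnt <- count_parameters(C, J)
  if (is.null(pi)) pi <- rep(1 / C, C)
  if (length(pi) != C || abs(sum(pi) - 1) > 1e-6)
    stop("pi must be a length-C simplex")
  if (any(pi <= 0))
    stop(sprintf("class %d has zero proportion; HBIC is undefined", which(pi <= 0)[1L]))
  aic <- -2 * loglik + 2 * cnt["n_k"]
  bic <- -2 * loglik + log(N) * cnt["n_k"]
  hbic <- -2 * loglik + cnt["n_k0"] * log(N) + sum((3 * J + 1) * log(pi * N))
  c(aic = unname(aic), bic = unname(bic), hbic = unname(hbic))
}

#' Entropy-based class separation
#'
#' Relative entropy reduction of the posterior classification:
#' `1 - sum_p sum_c (-post ln post) / (N ln C)`.  1 means perfectly
#' separated (degenerate posteriors), 0 means no separation (uniform
#' posteriors).
#'
#' @param posterior N x C posterior probability matrix (C >= 2).
#' @return Scalar in `[0, 1]`.
#' @export
r2_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  C <- ncol(posterior)
  if (C < 2L) stop("entropy-based separation is undefined for a single class")
  p <- pmax(posterior, 1e-300)
  H <- -sum(posterior * log(p))
  1 - H / (nrow(posterior) * log(C))
}

#' Fit and compare MixTree models with increasing class counts
#'
#' Fits MixTree-1 through MixTree-`max_classes` to the same data and tabulates
#' the selection criteria, separation and class sizes.
#'
#' @param responses response matrix.
#' @param max_classes largest number of classes to fit.
#' @param seed optional master seed (one child seed per fitted C).
#' @param ... passed to [mixtree()].
#' @return A `"mixtree_select"` data frame with one row per fitted C and the
#'   fits in `attr(, "fits")`.
#' @export
mixtree_select <- function(responses, max_classes = 4L, seed = NULL, ...) {
  seeds <- child_seeds(seed, max_classes)
  fits <- lapply(seq_len(max_classes), function(C)
    tryCatch(mixtree(responses, classes = C, seed = seeds[[C]], ...),
             error = function(e) e))
  rows <- lapply(seq_len(max_classes), function(C) {
    f <- fits[[C]]
    if (inherits(f, "error"))
      return(data.frame(C = C, loglik = NA_real_, aic = NA_real_,
                        bic = NA_real_, hbic = NA_real_,
                        n_k = count_parameters(C, ncol(as.matrix(responses)))["n_k"],
                        r2_entropy = NA_real_, mean_diag_accuracy = NA_real_))
    ic <- information_criteria(f)
    data.frame(C = C, loglik = f$loglik, aic = ic["aic"], bic = ic["bic"],
               hbic = ic["hbic"], n_k = unname(f$counts["n_k"]),
               r2_entropy = if (C > 1) r2_entropy(f$posterior) else NA_real_,
               mean_diag_accuracy = mean(diag(f$error_matrix)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pimat <- matrix(NA_real_, max_classes, max_classes,
                  dimnames = list(NULL, paste0("pi_", seq_len(max_classes))))
  for (C in seq_len(max_classes))
    if (!inherits(fits[[C]], "error")) pimat[C, seq_len(C)] <- fits[[C]]$params$pi
  out <- cbind(out, pimat)
  attr(out, "fits") <- fits
  class(out) <- c("mixtree_select", "data.frame")
  out
}

#' @export
print.mixtree_select <- function(x, ...) {
  cat("MixTree class enumeration\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  best <- x$C[which.min(x$aic)]
  cat(sprintf("\nAIC prefers C = %d; BIC prefers C = %d\n",
              best, x$C[which.min(x$bic)]))
  invisible(x)
}

#' Cohen's kappa for two categorical assignments
#'
#' @param a,b equal-length class index vectors.
#' @return Chance-corrected agreement; 1 for identical vectors, about 0 for
#'   independent assignments with matching margins.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- sort(unique(c(a, b)))
  ta <- tabulate(match(a, lev), length(lev)) / length(a)
  tb <- tabulate(match(b, lev), length(lev)) / length(b)
  po <- mean(a == b)
  pe <- sum(ta * tb)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' K-fold cross-validation diagnostics for a MixTree model
#'
#' Partitions respondents into `folds` random folds.  For each fold the
#' model is fitted independently on the training remainder and on the test
#' fold; class labels of the two fits are aligned with [align_labels()];
#' then the report compares (a) the stacked item-parameter vectors of the
#' two fits (correlation and signed mean difference), (b) on the test
#' respondents, EAP trait/ERS scores and class posteriors computed under the
#' train-fit versus test-fit parameters (correlation; mean absolute
#' difference for the scores), and (c) the two modal assignments (agreement
#' proportion and Cohen's kappa).
#'
#' @param responses response matrix.
#' @param classes number of classes C to fit.
#' @param folds number of folds (>= 2; remainder respondents are spread
#'   across folds).
#' @param seed optional seed for the fold split and fits.
#' @param ... passed to [mixtree()].
#' @return A `"mixtree_cv"` data frame: one row per fold plus `mean` and
#'   `sd` rows.
#' @export
kfold_cv <- function(responses, classes = 2L, folds = 5L, seed = NULL, ...) {
  y <- as.matrix(responses)
  N <- nrow(y)
  stopifnot(folds >= 2L, N >= 2L * folds)
  seeds <- child_seeds(seed, folds + 1L)
  fold_id <- with_seed(seeds[[folds + 1L]],
                       sample(rep_len(seq_len(folds), N)))
  rows <- lapply(seq_len(folds), function(k) {
    res <- tryCatch({
      tr <- y[fold_id != k, , drop = FALSE]
      te <- y[fold_id == k, , drop = FALSE]
      fit_tr <- mixtree(tr, classes = classes, seed = seeds[[k]], ...)
      fit_te <- suppressWarnings(
        mixtree(te, classes = classes, seed = seeds[[k]], ...))
      pa <- align_labels(fit_tr$params, fit_te$params)
      perm <- attr(pa, "permutation")
      iv_tr <- stack_item_params(fit_tr$params)
      iv_te <- stack_item_params(pa)
      eap_tr <- predict(fit_tr, newdata = te, type = "eap")
      eap_te <- fit_te$eap
      post_tr <- predict(fit_tr, newdata = te, type = "posterior")
      post_te <- fit_te$posterior[, perm, drop = FALSE]
      w_tr <- modal_assign(post_tr)
      w_te <- modal_assign(post_te)
      data.frame(fold = k,
                 item_cor = cor(iv_tr, iv_te),
                 item_dist = mean(iv_tr - iv_te),
                 trait_cor = cor(eap_tr$theta, eap_te$theta),
                 trait_dist = mean(abs(eap_tr$theta - eap_te$theta)),
                 ers_cor = cor(eap_tr$eta, eap_te$eta),
                 ers_dist = mean(abs(eap_tr$eta - eap_te$eta)),
                 post_cor = if (classes > 1) cor(as.vector(post_tr), as.vector(post_te)) else NA_real_,
                 hit = mean(w_tr == w_te),
                 kappa = if (classes > 1) cohen_kappa(w_tr, w_te) else NA_real_,
                 failed = FALSE)
    }, error = function(e) NULL)
    if (is.null(res))
      res <- data.frame(fold = k, item_cor = NA_real_, item_dist = NA_real_,
                        trait_cor = NA_real_, trait_dist = NA_real_,
                        ers_cor = NA_real_, ers_dist = NA_real_,
                        post_cor = NA_real_, hit = NA_real_, kappa = NA_real_,
                        failed = TRUE)
    res
  })
  tab <- do.call(rbind, rows)
  num <- tab[, setdiff(names(tab), c("fold", "failed"))]
  summ <- rbind(colMeans(num, na.rm = TRUE),
                apply(num, 2, sd, na.rm = TRUE))
  summary_tab <- data.frame(fold = c("mean", "sd"), summ,
                            failed = c(NA, NA))
  tab$fold <- as.character(tab$fold)
  out <- rbind(tab, summary_tab)
  rownames(out) <- NULL
  class(out) <- c("mixtree_cv", "data.frame")
  attr(out, "classes") <- classes
  attr(out, "folds") <- folds
  out
}

#' @export
print.mixtree_cv <- function(x, ...) {
  cat(sprintf("MixTree-%d %d-fold cross-validation\n",
              attr(x, "classes"), attr(x, "folds")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

## All measurement parameters stacked into one comparison vector,
## class-specific blocks in the (aligned) class order.
stack_item_params <- function(p) {
  c(p$alpha_trait, p$beta1, as.vector(p$omega), p$alpha_ers,
    as.vector(p$beta2), as.vector(p$beta3))
}
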