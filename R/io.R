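#' Read a response matrix from delimited text
#'
#' Reads a CSV with a header row of item labels and one row per respondent;
#' cells hold integer categories 1-4 and empty cells are missing.  Input is
#' validated cell by cell and a per-item category-frequency summary is
#' attached.
#'
#' @param path file path.
#' @param sep field separator.
#' @return Integer response matrix with attribute
#'   `"category_frequencies"` (4 x J counts).
#' @export
read_responses <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("response file is empty: ", path)
  y <- as.matrix(df)
  if (!is.numeric(y))
    storage.mode(y) <- "double"
  bad <- which(!is.na(y) & (y %% 1 != 0 | y < 1 | y > 4))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(y)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(y)) + 1L
    stop(sprintf("invalid response '%s' at row %d, column '%s' (expected integer 1-4 or empty)",
                 format(y[bad[1L]]), i, colnames(y)[j]))
  }
  storage.mode(y) <- "integer"
  attr(y, "category_frequencies") <-
    apply(y, 2, function(col) tabulate(col, 4L))
  y
}

#' Write a response matrix to CSV
#'
#' @param responses response matrix.
#' @param path file path.
#' @export
write_responses <- function(responses, path) {
  y <- as.matrix(responses)
  if (is.null(colnames(y))) colnames(y) <- paste0("item", seq_len(ncol(y)))
  write.csv(as.data.frame(y), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write result tables and a run log to a directory
#'
#' Exports the tables a reporting workflow needs as CSV: for a fitted model,
#' the class-invariant and class-specific parameter tables (classes in the
#' canonical descending-ERS-loading order), posterior matrix, assignments
#' and classification-error matrix plus a structured text log (call,
#' log-likelihood, per-start log-likelihoods, convergence); for a selection
#' report or cross-validation report, the table itself; for a covariate
#' model, coefficients with standard errors.  Numeric output is
#' deterministic given the fitted object, so re-running a seeded analysis
#' reproduces the files byte for byte.
#'
#' @param x a `"mixtree"`, `"mixtree_select"`, `"mixtree_cv"` or
#'   `"mixtree_covmod"` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  if (inherits(x, "mixtree")) {
    p <- x$params
    put(data.frame(item = seq_len(x$J), alpha_trait = p$alpha_trait,
                   beta1 = p$beta1), "parameters_invariant.csv")
    cls <- do.call(rbind, lapply(seq_len(x$C), function(cc)
      data.frame(class = cc, item = seq_len(x$J), omega = p$omega[, cc],
                 alpha_ers = p$alpha_ers[cc], beta2 = p$beta2[, cc],
                 beta3 = p$beta3[, cc], pi = p$pi[cc])))
    put(cls, "parameters_classes.csv")
    put(as.data.frame(x$posterior), "posterior.csv")
    put(data.frame(person = seq_len(x$N), assignment = x$assignment),
        "assignments.csv")
    put(as.data.frame(x$error_matrix), "error_matrix.csv")
    put(cbind(person = seq_len(x$N), x$eap), "eap_scores.csv")
    log_path <- file.path(dir, "run_log.txt")
    writeLines(c(
      paste("call:", paste(deparse(x$call), collapse = " ")),
      sprintf("classes: %d  persons: %d  items: %d", x$C, x$N, x$J),
      sprintf("loglik: %.6f", x$loglik),
      sprintf("free parameters: %d", x$npar),
      sprintf("latent correlation: %.6f", p$latent_corr),
      sprintf("starts: %d  converged: %s", x$n_starts, x$converged),
      paste("start logliks:", paste(sprintf("%.4f", x$start_logliks),
                                    collapse = " ")),
      sprintf("quadrature points per dimension: %d", x$quad_points)),
      log_path)
    paths <- c(paths, log_path)
  } else if (inherits(x, "mixtree_select")) {
    put(as.data.frame(unclass(x)), "selection_report.csv")
  } else if (inherits(x, "mixtree_cv")) {
    put(as.data.frame(unclass(x)), "cv_report.csv")
  } else if (inherits(x, "mixtree_covmod")) {
    put(data.frame(term = rownames(x$gamma),
                   do.call(cbind, list(estimate = x$gamma, se = x$se))),
        "covariate_model.csv")
  } else {
    stop("no report writer for objects of class ", class(x)[1L])
  }
  invisible(paths)
}

#' Export the pseudo-item decomposition to CSV
#'
#' Writes a 3J-column table named `<item>_node1/2/3`; structurally missing
#' cells are blank.
#'
#' @param pseudo a `"pseudo_items"` object (or a response matrix, which is
#'   decomposed first).
#' @param path file path.
#' @export
write_pseudo_items <- function(pseudo, path) {
  if (!inherits(pseudo, "pseudo_items")) pseudo <- pseudo_items(pseudo)
  items <- colnames(pseudo$y1)
  if (is.null(items)) items <- paste0("item", seq_len(pseudo$J))
  out <- vector("list", 3L * pseudo$J)
  nms <- character(3L * pseudo$J)
  for (j in seq_len(pseudo$J)) {
    for (t in 1:3) {
      out[[(j - 1L) * 3L + t]] <- pseudo[[paste0("y", t)]][, j]
      nms[(j - 1L) * 3L + t] <- paste0(items[j], "_node", t)
    }
  }
  df <- setNames(as.data.frame(out), nms)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
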