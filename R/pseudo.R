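#' Decompose four-point responses into tree pseudo-items
#'
#' Maps each ordinal response in \{1, 2, 3, 4\} to the binary outcomes of the
#' three tree nodes: `y1` (direction: 0 = disagreement side, 1 = agreement
#' side), `y2` (disagreement extremity: 1 = mild "2", 0 = extreme "1") and
#' `y3` (agreement extremity: 1 = extreme "4", 0 = mild "3").  A node that a
#' respondent never reaches is missing by design: `y2` is `NA` wherever
#' `y1 = 1` and `y3` is `NA` wherever `y1 = 0`.  A missing response leaves
#' all three nodes `NA`.
#'
#' @param responses integer matrix or data frame, persons in rows, items in
#'   columns, entries in \{1,2,3,4\} or `NA`.
#' @return An object of class `"pseudo_items"`: a list with `N x J` matrices
#'   `y1`, `y2`, `y3` and attribute-carried dimensions.
#' @examples
#' y <- matrix(c(1, 2, 3, 4), 2, 2)
#' p <- pseudo_items(y)
#' p$y1
#' @seealso [recompose_responses()] for the inverse map,
#'   [write_pseudo_items()] for CSV export.
#' @export
pseudo_items <- function(responses) {
  y <- as.matrix(responses)
  if (length(y) == 0L) stop("response matrix is empty")
  storage.mode(y) <- "double"
  bad <- which(!is.na(y) & !(y %in% c(1, 2, 3, 4)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(y)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(y)) + 1L
    stop(sprintf("invalid response category %s at row %d, column %d (must be 1-4 or NA)",
                 format(y[bad[1L]]), i, j))
  }
  y1 <- ifelse(is.na(y), NA_real_, as.numeric(y >= 3))
  y2 <- ifelse(!is.na(y) & y <= 2, as.numeric(y == 2), NA_real_)
  y3 <- ifelse(!is.na(y) & y >= 3, as.numeric(y == 4), NA_real_)
  dimnames(y1) <- dimnames(y2) <- dimnames(y3) <- dimnames(y)
  structure(list(y1 = y1, y2 = y2, y3 = y3, N = nrow(y), J = ncol(y)),
            class = "pseudo_items")
}

#' Recompose pseudo-items into ordinal responses
#'
#' Inverse of [pseudo_items()]: maps each (`y1`, `y2`, `y3`) triple back to
#' its unique category in \{1,2,3,4\}.
#'
#' @param pseudo a `"pseudo_items"` object.
#' @return Integer response matrix with `NA` where the direction node is
#'   missing.
#' @export
recompose_responses <- function(pseudo) {
  stopifnot(inherits(pseudo, "pseudo_items"))
  y1 <- pseudo$y1; y2 <- pseudo$y2; y3 <- pseudo$y3
  out <- matrix(NA_integer_, nrow(y1), ncol(y1), dimnames = dimnames(y1))
  out[which(y1 == 0 & y2 == 0)] <- 1L
  out[which(y1 == 0 & y2 == 1)] <- 2L
  out[which(y1 == 1 & y3 == 0)] <- 3L
  out[which(y1 == 1 & y3 == 1)] <- 4L
  out
}

#' @export
print.pseudo_items <- function(x, ...) {
  cat(sprintf("Pseudo-item decomposition: %d persons x %d items (3 nodes each)\n",
              x$N, x$J))
  cat(sprintf("  direction node observed: %d cells; extremity nodes observed: %d / %d\n",
              sum(!is.na(x$y1)), sum(!is.na(x$y2)), sum(!is.na(x$y3))))
  invisible(x)
}

## 0/1 indicator matrices with NA -> 0, used by the vectorised likelihood.
## A* carry y = 1 events, B* the y = 0 events; W1/V2/V3 mark observed nodes.
pseudo_indicators <- function(pseudo) {
  z <- function(m) { m[is.na(m)] <- 0; m }
  A1 <- z(pseudo$y1)
  W1 <- z((!is.na(pseudo$y1)) * 1)
  B1 <- W1 - A1
  A2 <- z(pseudo$y2)
  V2 <- z((!is.na(pseudo$y2)) * 1)
  B2 <- V2 - A2
  A3 <- z(pseudo$y3)
  V3 <- z((!is.na(pseudo$y3)) * 1)
  B3 <- V3 - A3
  list(A1 = A1, B1 = B1, W1 = W1, A2 = A2, B2 = B2, V2 = V2,
       A3 = A3, B3 = B3, V3 = V3, N = pseudo$N, J = pseudo$J)
}
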