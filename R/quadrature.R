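#' Bivariate normal quadrature grid
#'
#' Product Gauss-Hermite rule for the standard bivariate normal latent
#' density of (trait, ERS).  Raw abscissae are rescaled to the probabilist
#' convention and the second dimension is rotated by the Cholesky factor of
#' the correlation matrix, so `theta = x1` and
#' `eta = rho * x1 + sqrt(1 - rho^2) * x2`.  Weights sum to 1.
#'
#' @param n_points nodes per dimension (default 15).
#' @param corr trait-ERS correlation.
#' @return List with node vectors `theta`, `eta`, raw axes `x1`, `x2`,
#'   weights `w` (length `n_points^2`) and the inputs.
#' @export
quadrature_grid <- function(n_points = 15L, corr = 0) {
  stopifnot(n_points >= 2L, abs(corr) < 1)
  gh <- pracma::gaussHermite(n_points)
  x <- gh$x * sqrt(2)        # N(0,1) abscissae
  w <- gh$w / sqrt(pi)       # weights summing to 1
  g <- expand.grid(x1 = x, x2 = x)
  wg <- as.vector(outer(w, w))
  list(theta = g$x1,
       eta = corr * g$x1 + sqrt(1 - corr^2) * g$x2,
       x1 = g$x1, x2 = g$x2, w = wg,
       n_points = n_points, corr = corr)
}

## Update the eta axis of an existing grid for a new correlation value
## (used when the latent correlation is a free parameter).
grid_set_corr <- function(grid, corr) {
  grid$eta <- corr * grid$x1 + sqrt(1 - corr^2) * grid$x2
  grid$corr <- corr
  grid
}
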