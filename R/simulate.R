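#' Sample standard-normal covariates
#'
#' Draws N independent covariate vectors from a standard multivariate normal
#' with identity covariance.
#'
#' @param N respondents.
#' @param T number of covariates (the study design fixes 3).
#' @param seed optional seed.
#' @return N x T matrix with columns `z1..zT`.
#' @export
sample_covariates <- function(N, T = 3L, seed = NULL) {
  with_seed(seed, matrix(rnorm(N * T), N, T,
                         dimnames = list(NULL, paste0("z", seq_len(T)))))
}

#' Membership-regression coefficients of the simulation design
#'
#' Builds the (T+1) x C multinomial-logit coefficient matrix used to
#' generate class memberships.  The slopes are fixed across class-size
#' profiles: covariate 1 has a strong effect (-1 on the satisficing-like
#' class 2 column, +1 on class 3), covariate 2 a weak effect (+0.5 / -0.5)
#' and covariate 3 none; class 1 is the reference.  For the three-class
#' equal profile the intercepts are (0, -0.37, -0.37); for every other
#' profile the intercepts are calibrated numerically so that the marginal
#' class probabilities under standard-normal covariates hit the nominal
#' profile proportions.
#'
#' @param C 2 or 3 classes.
#' @param profile class-size profile: `"equal"`, `"dominant-first"`,
#'   `"dominant-middle"` (C = 3 only) or `"dominant-last"`.
#' @return (T+1) x C coefficient matrix with attribute `"nominal_pi"`.
#' @export
design_gamma <- function(C = 3L,
                         profile = c("equal", "dominant-first",
                                     "dominant-middle", "dominant-last")) {
  profile <- match.arg(profile)
  stopifnot(C %in% c(2L, 3L))
  slopes <- cbind(class1 = c(0, 0, 0),
                  class2 = c(-1, 0.5, 0),
                  class3 = c(1, -0.5, 0))[, seq_len(C), drop = FALSE]
  nominal <- switch(profile,
    "equal" = if (C == 2L) c(0.5, 0.5) else rep(1, 3) / 3,
    "dominant-first" = if (C == 2L) c(0.6, 0.4) else c(0.6, 0.2, 0.2),
    "dominant-middle" = { stopifnot(C == 3L); c(0.2, 0.6, 0.2) },
    "dominant-last" = if (C == 2L) c(0.4, 0.6) else c(0.2, 0.2, 0.6))
  if (C == 3L && profile == "equal") {
    g0 <- c(0, -0.37, -0.37)
  } else {
    g0 <- c(0, solve_intercepts(slopes, nominal))
  }
  gamma <- rbind(g0, slopes)
  dimnames(gamma) <- list(c("(Intercept)", "z1", "z2", "z3"),
                          paste0("class", seq_len(C)))
  attr(gamma, "nominal_pi") <- nominal
  gamma
}

## Calibrate free intercepts (classes 2..C) so that the covariate-marginal
## class probabilities equal `target` under standard-normal covariates.
## The expectation is computed on a fixed Gauss-Hermite product grid, so
## the calibration is deterministic.
solve_intercepts <- function(slopes, target, n_nodes = 10L) {
  C <- ncol(slopes)
  Tn <- nrow(slopes)
  gh <- pracma::gaussHermite(n_nodes)
  x <- gh$x * sqrt(2); w <- gh$w / sqrt(pi)
  active <- which(rowSums(abs(slopes)) > 0)
  grids <- expand.grid(rep(list(x), length(active)))
  wg <- apply(expand.grid(rep(list(w), length(active))), 1, prod)
  Z <- matrix(0, nrow(grids), Tn)
  Z[, active] <- as.matrix(grids)
  marg <- function(g0free) {
    P <- softmax_rows(cbind(1, Z) %*% rbind(c(0, g0free), slopes))
    colSums(P * wg)
  }
  res <- nlminb(rep(0, C - 1L),
                function(g) sum((marg(g) - target)^2),
                control = list(rel.tol = 1e-14))
  if (res$objective > 1e-8)
    warning("intercept calibration did not reach the nominal class sizes exactly")
  res$par
}

#' Sample true class memberships from covariates
#'
#' Evaluates the multinomial logistic membership model at each covariate row
#' and draws one class per respondent.
#'
#' @param covariates N x T matrix.
#' @param gamma (T+1) x C coefficient matrix (see [design_gamma()]).
#' @param seed optional seed.
#' @return List with `class` (length-N indices) and `probs` (N x C matrix).
#' @export
sample_memberships <- function(covariates, gamma, seed = NULL) {
  Z <- as.matrix(covariates)
  P <- softmax_rows(cbind(1, Z) %*% gamma)
  cum <- t(apply(P, 1, cumsum))
  cum[, ncol(cum)] <- 1
  cls <- with_seed(seed, {
    u <- runif(nrow(P))
    max.col(u < cum, ties.method = "first")
  })
  list(class = cls, probs = P)
}

#' Sample latent trait and ERS scores
#'
#' Bivariate normal with zero means, unit variances and the given
#' correlation.
#'
#' @param N respondents.
#' @param latent_corr trait-ERS correlation in (-1, 1).
#' @param seed optional seed.
#' @return List with numeric vectors `theta` and `eta`.
#' @export
sample_latent_scores <- function(N, latent_corr = 0, seed = NULL) {
  stopifnot(abs(latent_corr) < 1)
  with_seed(seed, {
    theta <- rnorm(N)
    eta <- latent_corr * theta + sqrt(1 - latent_corr^2) * rnorm(N)
    list(theta = theta, eta = eta)
  })
}

#' Sample item parameters for a simulation replication
#'
#' Direction-node parameters are class-invariant: trait loadings from
#' U(0.5, 1.25) and intercepts from N(0, 1).  Extremity-node parameters are
#' built around the balanced class (class 2 of the three response
#' strategies): `omega ~ U(0.5, 0.7)`, ERS loading `~ U(0.5, 0.7)` and
#' intercepts `~ N(0, 1)`.  The satisficing-dominated class subtracts a
#' separation-specific uniform increment from `omega` and adds it to the ERS
#' loading; the optimizing-dominated class does the opposite; both receive
#' independent normal intercept noise.  Offsets per separation level:
#' U(0, 0.1) / U(0.2, 0.3) / U(0.4, 0.5) for loadings and normal SD
#' 0.25 / 0.75 / 1.5 for intercepts (low / medium / high).  Offset-class
#' intercepts are truncated to \[-3, 3\].
#'
#' @param J items.
#' @param C_true 1, 2 or 3 classes.  With `C_true = 2` the satisficing and
#'   balanced strategies are used; with `C_true = 1` the single strategy
#'   named by `single_class_identity` (at medium separation by convention of
#'   the study design).
#' @param separation `"low"`, `"medium"` or `"high"` (only meaningful for
#'   `C_true > 1`).
#' @param latent_corr trait-ERS correlation stored in the parameter set.
#' @param pi nominal class proportions to store (default uniform).
#' @param single_class_identity which strategy column (1, 2, 3) a
#'   single-class population follows.
#' @param seed optional seed.
#' @return A [mixtree_params()] object.
#' @export
sample_item_parameters <- function(J, C_true = 2L,
                                   separation = c("high", "medium", "low"),
                                   latent_corr = 0, pi = NULL,
                                   single_class_identity = 2L, seed = NULL) {
  separation <- match.arg(separation)
  stopifnot(C_true %in% 1:3, single_class_identity %in% 1:3)
  if (C_true == 1L) separation <- "medium"
  off <- switch(separation, low = c(0, 0.1), medium = c(0.2, 0.3),
                high = c(0.4, 0.5))
  bsd <- switch(separation, low = 0.25, medium = 0.75, high = 1.5)
  with_seed(seed, {
    alpha_trait <- runif(J, 0.5, 1.25)
    beta1 <- rnorm(J)
    omega2 <- runif(J, 0.5, 0.7)
    ers2 <- runif(1, 0.5, 0.7)
    beta22 <- rnorm(J)
    beta32 <- rnorm(J)
    trunc3 <- function(x) pmin(pmax(x, -3), 3)
    mk <- function(strategy) {
      # strategy 1 = satisficing-dominated, 2 = balanced, 3 = optimizing-dominated
      sgn <- c(-1, 0, 1)[strategy]
      if (strategy == 2L)
        list(omega = omega2, ers = ers2, b2 = beta22, b3 = beta32)
      else
        list(omega = omega2 + sgn * runif(J, off[1], off[2]),
             ers = ers2 - sgn * runif(1, off[1], off[2]),
             b2 = trunc3(beta22 + rnorm(J, 0, bsd)),
             b3 = trunc3(beta32 + rnorm(J, 0, bsd)))
    }
    strategies <- if (C_true == 1L) single_class_identity else seq_len(C_true)
    blocks <- lapply(strategies, mk)
    if (is.null(pi)) pi <- rep(1 / C_true, C_true)
    mixtree_params(alpha_trait, beta1,
                   omega = sapply(blocks, `[[`, "omega"),
                   alpha_ers = vapply(blocks, `[[`, numeric(1), "ers"),
                   beta2 = sapply(blocks, `[[`, "b2"),
                   beta3 = sapply(blocks, `[[`, "b3"),
                   pi = pi, latent_corr = latent_corr)
  })
}

#' Generate responses from MixTree parameters
#'
#' Computes each respondent's category probabilities under their true class
#' and latent scores and draws one category per item.
#'
#' @param params a [mixtree_params()] object.
#' @param true_class length-N class indices.
#' @param scores list with vectors `theta` and `eta`.
#' @param seed optional seed.
#' @return N x J integer matrix with entries 1-4.
#' @export
generate_responses <- function(params, true_class, scores, seed = NULL) {
  N <- length(true_class)
  stopifnot(length(scores$theta) == N, length(scores$eta) == N,
            all(true_class %in% seq_len(params$C)))
  J <- params$J
  with_seed(seed, {
    y <- matrix(NA_integer_, N, J,
                dimnames = list(NULL, paste0("item", seq_len(J))))
    u <- matrix(runif(N * J), N, J)
    for (cc in sort(unique(true_class))) {
      rows <- which(true_class == cc)
      th <- scores$theta[rows]; et <- scores$eta[rows]
      a <- params$alpha_trait
      aw <- a * params$omega[, cc]
      e <- params$alpha_ers[cc]
      P1 <- plogis(outer(th, a) + rep(params$beta1, each = length(rows)))
      base <- outer(th, aw)
      P2 <- plogis(base - e * et + rep(params$beta2[, cc], each = length(rows)))
      P3 <- plogis(base + e * et + rep(params$beta3[, cc], each = length(rows)))
      c1 <- (1 - P1) * (1 - P2)
      c2 <- (1 - P1) * P2
      c3 <- P1 * (1 - P3)
      uu <- u[rows, , drop = FALSE]
      y[rows, ] <- 1L + (uu > c1) + (uu > c1 + c2) + (uu > c1 + c2 + c3)
    }
    y
  })
}

#' Generate one synthetic MixTree data set
#'
#' Runs the full generating process of the simulation design: standard
#' multivariate-normal covariates; class memberships from the multinomial
#' logistic membership model (skipped for a one-class population, whose
#' covariates are unrelated to anything); bivariate-normal latent scores;
#' item parameters drawn for the requested separation level; responses from
#' the class-specific category probabilities.
#'
#' @param N respondents (the study design uses 1000, 2000, 3000).
#' @param J items (10, 20, 30).
#' @param C number of true classes (1, 2 or 3).
#' @param profile class-size profile, see [design_gamma()].
#' @param separation class separation (`"low"`, `"medium"`, `"high"`).
#' @param latent_corr trait-ERS correlation (0 or 0.30 in the design).
#' @param single_class_identity strategy followed by a one-class population.
#' @param seed optional seed (controls every draw).
#' @return An object of class `"mixtree_sim"`: list with `responses`,
#'   `covariates`, `true_class`, `class_probs`, `scores`, `params`, `gamma`
#'   and the design settings.
#' @export
sim_mixtree_data <- function(N, J, C = 2L, profile = "equal",
                             separation = "high", latent_corr = 0,
                             single_class_identity = 2L, seed = NULL) {
  with_seed(seed, {
    covariates <- sample_covariates(N)
    if (C > 1L) {
      gamma <- design_gamma(C, profile)
      mem <- sample_memberships(covariates, gamma)
      true_class <- mem$class
      class_probs <- mem$probs
      pi <- attr(gamma, "nominal_pi")
    } else {
      gamma <- NULL
      true_class <- rep(1L, N)
      class_probs <- matrix(1, N, 1)
      pi <- 1
    }
    scores <- sample_latent_scores(N, latent_corr)
    params <- sample_item_parameters(J, C, separation, latent_corr, pi = pi,
                                     single_class_identity = single_class_identity)
    responses <- generate_responses(params, true_class, scores)
    structure(list(responses = responses, covariates = covariates,
                   true_class = true_class, class_probs = class_probs,
                   scores = scores, params = params, gamma = gamma,
                   design = list(N = N, J = J, C = C, profile = profile,
                                 separation = if (C > 1L) separation else "medium",
                                 latent_corr = latent_corr,
                                 single_class_identity = single_class_identity)),
              class = "mixtree_sim")
  })
}

#' @export
print.mixtree_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf("Synthetic MixTree data: N = %d, J = %d, C = %d (%s, %s separation, corr %.2f)\n",
              d$N, d$J, d$C, d$profile, d$separation, d$latent_corr))
  cat("  realized class proportions:",
      paste(sprintf("%.3f", tabulate(x$true_class, max(x$true_class)) / d$N),
            collapse = " "), "\n")
  invisible(x)
}

#' Enumerate the factorial simulation design
#'
#' Tabulates every cell of the study's factorial design: mixture populations
#' cross 7 (C, class-size-profile) combinations with 3 test lengths, 3
#' sample sizes, 2 latent correlations and 3 separation levels; one-class
#' populations cross 3 strategy identities with the same test lengths,
#' sample sizes and correlations at a single (medium) separation.
#'
#' @param reps replications per cell (the study uses 200).
#' @return Data frame of design cells with a `reps` column; attributes
#'   `"n_mixture"` and `"n_nonmixture"` carry the generated-data-set totals.
#' @export
design_grid <- function(reps = 200L) {
  profiles2 <- c("equal", "dominant-first", "dominant-last")
  profiles3 <- c("equal", "dominant-first", "dominant-middle", "dominant-last")
  mix <- rbind(
    expand.grid(C = 2L, profile = profiles2, J = c(10L, 20L, 30L),
                N = c(1000L, 2000L, 3000L), latent_corr = c(0, 0.30),
                separation = c("low", "medium", "high"),
                stringsAsFactors = FALSE),
    expand.grid(C = 3L, profile = profiles3, J = c(10L, 20L, 30L),
                N = c(1000L, 2000L, 3000L), latent_corr = c(0, 0.30),
                separation = c("low", "medium", "high"),
                stringsAsFactors = FALSE))
  mix$single_class_identity <- NA_integer_
  non <- expand.grid(C = 1L, profile = "equal", J = c(10L, 20L, 30L),
                     N = c(1000L, 2000L, 3000L), latent_corr = c(0, 0.30),
                     separation = "medium", stringsAsFactors = FALSE)
  non <- merge(non, data.frame(single_class_identity = 1:3))
  non <- non[, names(mix)]
  grid <- rbind(mix, non)
  grid$reps <- reps
  attr(grid, "n_mixture") <- nrow(mix) * reps
  attr(grid, "n_nonmixture") <- nrow(non) * reps
  grid
}

#' Parameter and classification recovery metrics
#'
#' Compares a fitted model against the generating truth after aligning the
#' class labels.  Reports, per parameter family (and per class for
#' class-specific families), the mean bias and RMSE across the parameters of
#' this replication; the classification hit rate (proportion assigned to
#' their true class); within-true-class mean bias, RMSE and mean posterior
#' SE of the EAP trait and ERS scores; and, if a covariate model and true
#' coefficients are supplied, bias and RMSE of the membership-regression
#' slopes.
#'
#' @param truth a `"mixtree_sim"` object.
#' @param fit a `"mixtree"` fit with the same number of classes as the truth
#'   (label alignment and hit rate require it; score metrics work for any C).
#' @param covmodel optional `"mixtree_covmod"` fit.
#' @param true_gamma optional true coefficient matrix for the covariate
#'   model.
#' @return Data frame with columns `family`, `class`, `bias`, `rmse`,
#'   `mean_se` and attribute `"hit_rate"`.
#' @export
evaluate_recovery <- function(truth, fit, covmodel = NULL, true_gamma = NULL) {
  stopifnot(inherits(truth, "mixtree_sim"), inherits(fit, "mixtree"))
  tp <- truth$params
  same_C <- fit$C == tp$C
  perm <- seq_len(fit$C)
  est <- fit$params
  if (same_C && fit$C > 1L) {
    est <- align_labels(tp, est)
    perm <- attr(est, "permutation")
  }
  row1 <- function(family, class, err, se = NA_real_)
    data.frame(family = family, class = class, bias = mean(err),
               rmse = sqrt(mean(err^2)), mean_se = se)
  rows <- list(row1("alpha_trait", NA, est$alpha_trait - tp$alpha_trait),
               row1("beta1", NA, est$beta1 - tp$beta1))
  if (same_C) {
    for (cc in seq_len(tp$C)) {
      rows <- c(rows, list(
        row1("omega", cc, est$omega[, cc] - tp$omega[, cc]),
        row1("alpha_ers", cc, est$alpha_ers[cc] - tp$alpha_ers[cc]),
        row1("beta2", cc, est$beta2[, cc] - tp$beta2[, cc]),
        row1("beta3", cc, est$beta3[, cc] - tp$beta3[, cc]),
        row1("pi", cc, est$pi[cc] - mean(truth$true_class == cc))))
    }
  }
  for (cc in sort(unique(truth$true_class))) {
    sel <- truth$true_class == cc
    rows <- c(rows, list(
      row1("trait_score", cc, fit$eap$theta[sel] - truth$scores$theta[sel],
           mean(fit$eap$se_theta[sel])),
      row1("ers_score", cc, fit$eap$eta[sel] - truth$scores$eta[sel],
           mean(fit$eap$se_eta[sel]))))
  }
  if (!is.null(covmodel) && !is.null(true_gamma)) {
    # re-reference after label alignment: aligned class k carries the old
    # column perm[k], and coefficients are relative to the new class 1
    est_g <- covmodel$gamma[, perm, drop = FALSE]
    est_g <- est_g - est_g[, 1L]
    err <- est_g[-1L, -1L] - true_gamma[-1L, -1L]
    rows <- c(rows, list(row1("gamma_slope", NA, as.vector(err))))
  }
  out <- do.call(rbind, rows)
  hit <- if (same_C) {
    # estimated label w corresponds to aligned (truth-order) label match(w, perm)
    mean(match(fit$assignment, perm) == truth$true_class)
  } else NA_real_
  attr(out, "hit_rate") <- hit
  out
}

#' Run a (scaled-down) simulation design grid
#'
#' For each requested design cell and replication: generates a data set,
#' fits MixTree models with 1 to `max_classes` classes, records fit and
#' selection quantities for every fitted model, and recovery metrics for the
#' correctly specified fit.  Failures in a replication are recorded and
#' skipped, never fatal.
#'
#' @param cells data frame of design cells as produced by [design_grid()]
#'   (any subset of rows).
#' @param reps replications per cell.
#' @param max_classes largest fitted class count.
#' @param seed master seed; each replication receives a derived child seed,
#'   so the same master seed reproduces the same table.
#' @param ... passed to [mixtree()] (e.g. `n_starts`, `quad_points`).
#' @return Tidy data frame with one row per (cell, rep, fitted C).
#' @export
run_design_grid <- function(cells, reps = 1L, max_classes = 3L, seed = NULL,
                            ...) {
  cells <- as.data.frame(cells)
  seeds <- child_seeds(seed, nrow(cells) * reps)
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    for (r in seq_len(reps)) {
      k <- k + 1L
      res <- tryCatch({
        sim <- sim_mixtree_data(
          N = cell$N, J = cell$J, C = cell$C, profile = cell$profile,
          separation = cell$separation, latent_corr = cell$latent_corr,
          single_class_identity = if (is.na(cell$single_class_identity)) 2L
                                  else cell$single_class_identity,
          seed = seeds[[k]])
        fits <- lapply(seq_len(max_classes), function(C)
          tryCatch(suppressWarnings(
            mixtree(sim$responses, classes = C, seed = seeds[[k]], ...)),
            error = function(e) NULL))
        aics <- vapply(fits, function(f) if (is.null(f)) NA_real_
                       else unname(information_criteria(f)["aic"]), numeric(1))
        sel <- if (all(is.na(aics))) NA_integer_ else which.min(aics)
        do.call(rbind, lapply(seq_len(max_classes), function(C) {
          f <- fits[[C]]
          base <- data.frame(cell = i, rep = r, C_true = cell$C,
                             N = cell$N, J = cell$J,
                             separation = cell$separation,
                             fitted_C = C, selected_by_aic = identical(sel, C))
          if (is.null(f)) {
            base$loglik <- NA_real_; base$aic <- NA_real_
            base$hit_rate <- NA_real_
            return(base)
          }
          ic <- information_criteria(f)
          base$loglik <- f$loglik; base$aic <- unname(ic["aic"])
          base$hit_rate <- if (C == cell$C)
            attr(evaluate_recovery(sim, f), "hit_rate") else NA_real_
          base
        }))
      }, error = function(e) NULL)
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}
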