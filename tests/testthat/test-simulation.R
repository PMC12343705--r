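test_that("covariates are independent standard normals, reproducibly", {
  Z <- sample_covariates(3000, seed = 51)
  expect_equal(dim(Z), c(3000, 3))
  expect_true(all(abs(colMeans(Z)) < 4 / sqrt(3000)))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 0.08))
  expect_lt(max(abs(cor(Z)[lower.tri(diag(3))])), 0.08)
  expect_identical(Z, sample_covariates(3000, seed = 51))
})

test_that("the equal-three-class membership model matches its printed form", {
  g <- design_gamma(3, "equal")
  expect_equal(unname(g[1, ]), c(0, -0.37, -0.37))
  expect_equal(unname(g["z1", ]), c(0, -1, 1))
  expect_equal(unname(g["z2", ]), c(0, 0.5, -0.5))
  expect_equal(unname(g["z3", ]), c(0, 0, 0))
  # two-class condition drops the last column; slopes are retained
  g2 <- design_gamma(2, "equal")
  expect_equal(unname(g2["z1", ]), c(0, -1))
  expect_equal(unname(g2["z2", ]), c(0, 0.5))
})

test_that("calibrated intercepts hit the nominal class sizes", {
  for (spec_ in list(list(C = 2, p = "dominant-first", nom = c(0.6, 0.4)),
                     list(C = 3, p = "dominant-last", nom = c(0.2, 0.2, 0.6)),
                     list(C = 2, p = "equal", nom = c(0.5, 0.5)))) {
    g <- design_gamma(spec_$C, spec_$p)
    expect_equal(attr(g, "nominal_pi"), spec_$nom)
    # independent Monte-Carlo check of the marginal class probabilities
    set.seed(52)
    Z <- matrix(rnorm(3e5), 1e5, 3)
    marg <- colMeans(predict_class_probs(g, Z))
    expect_equal(unname(marg), spec_$nom, tolerance = 0.02)
  }
})

test_that("sampled memberships track the membership probabilities", {
  Z <- sample_covariates(3000, seed = 53)
  g <- design_gamma(3, "equal")
  mem <- sample_memberships(Z, g, seed = 54)
  expect_lt(max(abs(as.vector(predict_class_probs(g, c(0, 0, 0))) -
                    c(0.4199, 0.2901, 0.2901))), 1e-4)
  realized <- tabulate(mem$class, 3) / 3000
  expect_true(all(abs(realized - 1 / 3) <= 0.10))
  expect_equal(rowSums(mem$probs), rep(1, 3000), tolerance = 1e-12)
  flat <- matrix(0, 4, 3)
  mem0 <- sample_memberships(Z, flat, seed = 55)
  expect_true(all(abs(tabulate(mem0$class, 3) / 3000 - 1 / 3) < 0.05))
})

test_that("latent scores have unit scales and the requested correlation", {
  for (rho in c(0, 0.30)) {
    sc <- sample_latent_scores(3000, rho, seed = 56)
    expect_lt(abs(cor(sc$theta, sc$eta) - rho), 0.05)
    expect_lt(abs(sd(sc$theta) - 1), 0.06)
    expect_lt(abs(sd(sc$eta) - 1), 0.06)
  }
  s1 <- sample_latent_scores(50, 0.3, seed = 57)
  s2 <- sample_latent_scores(50, 0.3, seed = 57)
  expect_identical(s1, s2)
})

test_that("item parameters respect the separation construction", {
  p <- sample_item_parameters(30, 3, "high", seed = 58)
  d1 <- p$omega[, 2] - p$omega[, 1]
  d3 <- p$omega[, 3] - p$omega[, 2]
  expect_true(all(d1 >= 0.4 & d1 <= 0.5))
  expect_true(all(d3 >= 0.4 & d3 <= 0.5))
  expect_true(all(p$omega[, 2] >= 0.5 & p$omega[, 2] <= 0.7))
  expect_gt(p$alpha_ers[1], p$alpha_ers[2])
  expect_gt(p$alpha_ers[2], p$alpha_ers[3])
  expect_true(all(p$beta2 >= -3 & p$beta2 <= 3))
  expect_true(all(p$beta3 >= -3 & p$beta3 <= 3))
  expect_true(all(p$alpha_trait >= 0.5 & p$alpha_trait <= 1.25))
  # repeated draws: the satisficing class always out-loads the optimizing
  # class on ERS under medium/high separation
  for (s in 1:10) {
    pm <- sample_item_parameters(10, 3, "medium", seed = 100 + s)
    expect_gt(pm$alpha_ers[1], pm$alpha_ers[3])
  }
  # two-class populations use the satisficing and balanced strategies
  p2 <- sample_item_parameters(10, 2, "high", seed = 59)
  expect_equal(p2$C, 2)
  expect_gt(p2$alpha_ers[1], p2$alpha_ers[2])
  # single-class populations follow one named strategy at medium separation
  p1 <- sample_item_parameters(10, 1, "high", single_class_identity = 2, seed = 60)
  expect_equal(p1$C, 1)
  expect_true(all(p1$omega >= 0.5 & p1$omega <= 0.7))
})

test_that("generated responses follow the model's category probabilities", {
  pars <- tiny_params(J = 4, C = 2)
  set.seed(61)
  N <- 3000
  cls <- sample(1:2, N, replace = TRUE)
  sc <- sample_latent_scores(N, 0.2, seed = 62)
  y <- generate_responses(pars, cls, sc, seed = 63)
  expect_true(all(y %in% 1:4))
  # empirical category frequencies vs. averaged model probabilities
  for (j in 1:4) {
    pmat <- matrix(0, N, 4)
    for (cc in 1:2) {
      rows <- cls == cc
      pmat[rows, ] <- category_probabilities(pars, sc$theta[rows],
                                             sc$eta[rows], j, cc)
    }
    expected <- colMeans(pmat)
    observed <- tabulate(y[, j], 4) / N
    se <- sqrt(expected * (1 - expected) / N)
    expect_true(all(abs(observed - expected) < 3.5 * se + 1e-4))
  }
  expect_identical(y, generate_responses(pars, cls, sc, seed = 63))
})

test_that("extreme parameters push responses into the top category", {
  pars <- flat_params(beta1 = 12, beta2 = 0, beta3 = 12)
  y <- generate_responses(pars, rep(1, 500), sample_latent_scores(500, 0, seed = 64),
                          seed = 65)
  expect_gt(mean(y == 4), 0.99)
})

test_that("the full generator wires covariates, classes and responses together", {
  sim <- sim_mixtree_data(N = 500, J = 8, C = 2, separation = "high",
                          latent_corr = 0.3, seed = 66)
  expect_equal(dim(sim$responses), c(500, 8))
  expect_equal(length(sim$true_class), 500)
  expect_equal(sim$params$C, 2)
  expect_identical(sim$responses,
                   sim_mixtree_data(N = 500, J = 8, C = 2, separation = "high",
                                    latent_corr = 0.3, seed = 66)$responses)
  sim1 <- sim_mixtree_data(N = 300, J = 5, C = 1, seed = 67)
  expect_true(all(sim1$true_class == 1))
  expect_equal(sim1$design$separation, "medium")
})

test_that("recovery metrics are exact for a perfect fit and obey Jensen", {
  sim <- sim_mixtree_data(N = 400, J = 6, C = 2, separation = "high", seed = 68)
  perfect <- structure(list(params = sim$params, C = 2L, J = 6L,
                            eap = data.frame(theta = sim$scores$theta,
                                             se_theta = 1,
                                             eta = sim$scores$eta, se_eta = 1),
                            assignment = sim$true_class),
                       class = "mixtree")
  rec <- evaluate_recovery(sim, perfect)
  item_rows <- rec$family %in% c("alpha_trait", "beta1", "omega", "alpha_ers",
                                 "beta2", "beta3")
  expect_true(all(abs(rec$bias[item_rows]) < 1e-12))
  expect_true(all(rec$rmse[item_rows] < 1e-12))
  expect_true(all(rec$rmse >= abs(rec$bias) - 1e-12))
  expect_equal(attr(rec, "hit_rate"), 1)
})

test_that("bias and RMSE follow their defining formulas", {
  sim <- sim_mixtree_data(N = 200, J = 2, C = 1, seed = 69)
  est <- sim$params
  est$alpha_trait <- sim$params$alpha_trait + c(0.1, -0.1)
  fake <- structure(list(params = est, C = 1L, J = 2L,
                         eap = data.frame(theta = sim$scores$theta, se_theta = 1,
                                          eta = sim$scores$eta, se_eta = 1),
                         assignment = rep(1L, 200)),
                    class = "mixtree")
  rec <- evaluate_recovery(sim, fake)
  r <- rec[rec$family == "alpha_trait", ]
  expect_equal(r$bias, 0, tolerance = 1e-12)
  expect_equal(r$rmse, 0.1, tolerance = 1e-12)
})

test_that("the factorial enumeration reproduces the design totals", {
  grid <- design_grid(reps = 200)
  expect_equal(attr(grid, "n_mixture"), 75600)
  expect_equal(attr(grid, "n_nonmixture"), 10800)
  expect_equal(sum(grid$reps), 86400)
  expect_equal(nrow(grid[grid$C > 1, ]), 378)   # 7 x 3 x 3 x 2 x 3
  expect_equal(nrow(grid[grid$C == 1, ]), 54)   # 3 x 3 x 3 x 2 x 1
})

test_that("a one-cell grid run fits one model per class count", {
  cells <- data.frame(C = 2L, profile = "equal", J = 5L, N = 300L,
                      latent_corr = 0, separation = "high",
                      single_class_identity = NA_integer_)
  suppressWarnings(
    out <- run_design_grid(cells, reps = 1, max_classes = 2, seed = 70,
                           n_starts = 1, quad_points = 5, max_iter = 40))
  expect_equal(nrow(out), 2)
  expect_equal(out$fitted_C, 1:2)
  expect_equal(sum(out$selected_by_aic), 1)
  expect_true(is.na(out$hit_rate[1]) && !is.na(out$hit_rate[2]))
})
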