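# Fitting tests run on deliberately small problems (N in the hundreds,
# few quadrature points) so the whole file stays fast; the full-scale
# behaviour of the estimator is exercised in test-acceptance.R.

test_that("fitting is deterministic given a seed", {
  sim <- sim_mixtree_data(N = 300, J = 6, C = 2, separation = "high", seed = 81)
  suppressWarnings({
    f1 <- mixtree(sim$responses, classes = 2, n_starts = 2, quad_points = 5,
                  max_iter = 40, seed = 82)
    f2 <- mixtree(sim$responses, classes = 2, n_starts = 2, quad_points = 5,
                  max_iter = 40, seed = 82)
  })
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$omega, f2$params$omega)
  expect_identical(f1$start_logliks, f2$start_logliks)
})

test_that("a richer class structure cannot fit worse than a single class", {
  sim <- sim_mixtree_data(N = 500, J = 8, C = 2, separation = "high", seed = 83)
  f1 <- mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 5,
                max_iter = 150, seed = 84)
  f2 <- mixtree(sim$responses, classes = 2, n_starts = 2, quad_points = 5,
                max_iter = 150, seed = 85)
  expect_gt(f2$loglik, f1$loglik)
})

test_that("the monitored log-likelihood never decreases along a run", {
  sim <- sim_mixtree_data(N = 400, J = 6, C = 2, separation = "high", seed = 86)
  f <- suppressWarnings(
    mixtree(sim$responses, classes = 2, n_starts = 1, quad_points = 7,
            max_iter = 120, seed = 87))
  expect_true(all(diff(f$trace) >= -1e-8 * (abs(f$loglik) + 1)))
})

test_that("class labels are reported in descending ERS-loading order", {
  sim <- sim_mixtree_data(N = 600, J = 8, C = 2, separation = "high", seed = 88)
  f <- mixtree(sim$responses, classes = 2, n_starts = 2, quad_points = 5,
               max_iter = 150, seed = 89)
  expect_true(all(diff(f$params$alpha_ers) <= 0))
  expect_equal(sum(f$params$pi), 1, tolerance = 1e-12)
  expect_equal(rowSums(f$posterior), rep(1, 600), tolerance = 1e-10)
  expect_equal(rowSums(f$error_matrix), rep(1, 2), tolerance = 1e-10)
})

test_that("single-class parameter recovery is accurate at scale", {
  sim <- sim_mixtree_data(N = 2000, J = 20, C = 1, seed = 90)
  f <- mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 9,
               seed = 91)
  expect_true(f$converged)
  expect_gt(cor(f$params$alpha_trait, sim$params$alpha_trait), 0.95)
  expect_lt(abs(mean(f$params$alpha_trait - sim$params$alpha_trait)), 0.05)
  expect_lt(abs(mean(f$params$beta1 - sim$params$beta1)), 0.05)
  expect_gt(cor(f$params$beta1, sim$params$beta1), 0.98)
})

test_that("small samples trigger the stability warning", {
  sim <- sim_mixtree_data(N = 150, J = 5, C = 1, seed = 92)
  expect_warning(
    mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 5,
            max_iter = 30, seed = 93),
    "fewer than 200")
})

test_that("fit summaries expose the selection quantities", {
  sim <- sim_mixtree_data(N = 400, J = 6, C = 2, separation = "high", seed = 94)
  f <- suppressWarnings(
    mixtree(sim$responses, classes = 2, n_starts = 1, quad_points = 5,
            max_iter = 80, seed = 95))
  s <- summary(f)
  expect_s3_class(s, "summary.mixtree")
  expect_equal(nrow(s$classes), 2)
  expect_equal(unname(AIC(f)), unname(information_criteria(f)["aic"]),
               tolerance = 1e-9)
  expect_output(print(f), "MixTree-2")
  expect_output(print(s), "Class summary")
})

test_that("prediction on new data matches training-data scoring", {
  sim <- sim_mixtree_data(N = 400, J = 6, C = 2, separation = "high", seed = 96)
  f <- suppressWarnings(
    mixtree(sim$responses, classes = 2, n_starts = 1, quad_points = 7,
            max_iter = 100, seed = 97))
  post <- predict(f, newdata = sim$responses, type = "posterior")
  expect_equal(post, f$posterior, tolerance = 1e-10)
  eap <- predict(f, newdata = sim$responses[1:5, ], type = "eap")
  expect_equal(eap, f$eap[1:5, ], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(predict(f, type = "class"), f$assignment)
})

test_that("simulate() round-trips through the generator", {
  sim <- sim_mixtree_data(N = 300, J = 5, C = 1, seed = 98)
  f <- mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 5,
               max_iter = 60, seed = 99)
  ys <- simulate(f, nsim = 2, seed = 100, N = 50)
  expect_length(ys, 2)
  expect_true(all(vapply(ys, function(y) all(dim(y) == c(50, 5)), logical(1))))
  expect_true(all(unlist(ys) %in% 1:4))
})

test_that("AIC df bookkeeping matches the free-parameter count", {
  sim <- sim_mixtree_data(N = 300, J = 5, C = 1, seed = 101)
  f <- mixtree(sim$responses, classes = 1, n_starts = 1, quad_points = 5,
               max_iter = 60, seed = 102)
  expect_equal(attr(logLik(f), "df"), unname(count_parameters(1, 5)["n_k"]))
})
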