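test_that("the Gaussian NLL matches a hand-summed SSE on a tiny series", {
  ds <- make_fixture("tiny_3pt")
  m <- rom_model(1)
  p <- c(a1 = 0.1, a2 = 0.05)
  # generating parameters: perfect fit, SSE term zero
  expect_equal(negative_log_likelihood(m, p, ds, sigma = 1), 0,
               tolerance = 1e-8)
  # brute-force SSE at different parameters
  q <- c(a1 = 0.2, a2 = 0.1)
  tr <- rom_integrate(m, q, c(2, 0), ds$experiments[[1]]$times)
  sse <- sum((tr$states - ds$experiments[[1]]$observed)^2)
  expect_equal(negative_log_likelihood(m, q, ds, sigma = 1), sse / 2,
               tolerance = 1e-6)
  expect_equal(negative_log_likelihood(m, q, ds, sigma = 2),
               6 * log(2) + sse / 8, tolerance = 1e-6)
  # concentrated form profiles sigma out
  expect_equal(negative_log_likelihood(m, q, ds), 3 * log(sse / 6),
               tolerance = 1e-6)
  expect_error(negative_log_likelihood(m, q, ds, sigma = 0), "sigma")
})

test_that("quadratic profiles give the closed-form chi-square interval", {
  a <- 3.7
  theta_hat <- 1.2
  grid <- seq(-3, 6, length.out = 401)
  prof <- list(grid = grid, profile_nll = a * (grid - theta_hat)^2)
  ci <- confidence_interval(prof, 0.95)
  half <- sqrt(stats::qchisq(0.95, 1) / 2 / a)
  expect_equal(unname(ci[1]), theta_hat - half, tolerance = 1e-4)
  expect_equal(unname(ci[2]), theta_hat + half, tolerance = 1e-4)
  # interval symmetric about the minimum
  expect_equal(unname(ci[2] - theta_hat), unname(theta_hat - ci[1]),
               tolerance = 1e-4)
  expect_true(attr(ci, "identifiable"))
  # the crossing is found by linear interpolation: on an exactly piecewise
  # linear profile the endpoints are exact
  lin <- list(grid = c(0, 1, 2, 3, 4),
              profile_nll = abs(c(0, 1, 2, 3, 4) - 2) * 4)
  ci2 <- confidence_interval(lin, 0.95)
  thr <- stats::qchisq(0.95, 1) / 2
  expect_equal(unname(ci2[1]), 2 - thr / 4, tolerance = 1e-12)
  expect_equal(unname(ci2[2]), 2 + thr / 4, tolerance = 1e-12)
})

test_that("flat profiles are reported as unbounded and non-identifiable", {
  prof <- list(grid = seq(0.1, 10, length.out = 21),
               profile_nll = rep(5, 21))
  ci <- confidence_interval(prof)
  expect_equal(as.numeric(ci), c(-Inf, Inf), ignore_attr = TRUE)
  expect_false(attr(ci, "identifiable"))
})

test_that("least squares recovers generating rates from a warm start", {
  ds <- make_fixture("model1_clean")
  truth <- c(a1 = 0.1, a2 = 0.05)
  # warm start within 10x of truth
  fit <- fit_least_squares(rom_model(1), ds, init = truth * 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params - truth) / truth), 0.01)
  expect_lt(fit$mae, 1e-5)
  # an already-optimal start terminates without moving
  fit2 <- fit_least_squares(rom_model(1), ds, init = truth)
  expect_lt(max(abs(fit2$params - truth)), 1e-6)
})

test_that("profile likelihood is minimized at the estimate and brackets it", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05),
                         y0 = c(1, 3), n_points = 40, t_end = 60,
                         noise_sd = 0.02, seed = 31)
  m <- rom_model(1)
  base <- fit_least_squares(m, ds, init = c(a1 = 0.2, a2 = 0.1))
  pr <- profile_likelihood(m, ds, base$params, "a1", n_grid = 9)
  expect_s3_class(pr, "rom_profile")
  # the profile at the estimate equals the global optimum NLL
  i_hat <- which(pr$grid == pr$mle_value)
  expect_equal(pr$profile_nll[i_hat], pr$nll_min, tolerance = 1e-6)
  # re-optimization can only do worse than the joint optimum
  nll_glob <- negative_log_likelihood(m, base$params, ds)
  expect_true(all(pr$profile_nll >= nll_glob - 1e-6))
  # roughly convex around the optimum: nondecreasing away from the minimum
  expect_true(all(diff(pr$profile_nll[pr$grid >= pr$mle_value]) > -1e-6))
  expect_true(all(diff(rev(pr$profile_nll[pr$grid <= pr$mle_value])) > -1e-6))
  # the CI contains the estimate and, here, the truth
  expect_lte(pr$ci_95[[1]], pr$mle_value)
  expect_gte(pr$ci_95[[2]], pr$mle_value)
  # confint method agrees
  cm <- confint(pr)
  expect_equal(unname(cm[1, ]), unname(as.numeric(pr$ci_95)))
  # unknown parameter and non-bracketing grid are rejected
  expect_error(profile_likelihood(m, ds, base$params, "a9"), "not a rate")
  expect_error(profile_likelihood(m, ds, base$params, "a1",
                                  grid = c(10, 20)), "bracket")
})

test_that("lower noise gives a tighter profile interval", {
  m <- rom_model(1)
  width <- vapply(c(0.01, 0.05), function(sd) {
    ds <- generate_dataset(m, c(a1 = 0.1, a2 = 0.05), y0 = c(1, 3),
                           n_points = 40, t_end = 60, noise_sd = sd,
                           seed = 77)
    base <- fit_least_squares(m, ds, init = c(a1 = 0.2, a2 = 0.1))
    pr <- profile_likelihood(m, ds, base$params, "a1", n_grid = 9)
    pr$ci_95[[2]] - pr$ci_95[[1]]
  }, numeric(1))
  expect_true(all(is.finite(width)))
  expect_lte(width[1], width[2])
})
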