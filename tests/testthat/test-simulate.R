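test_that("integration is exact for degenerate kinetics", {
  m <- rom_model(1)
  tt <- seq(0, 50, length.out = 20)
  # all rates zero: constant trajectory
  tr <- rom_integrate(m, c(a1 = 0, a2 = 0), c(3, 1), tt)
  expect_equal(tr$states, matrix(c(3, 1), 20, 2, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-10)
  # detailed-balance initial condition stays put
  tr2 <- rom_integrate(m, c(a1 = 1, a2 = 1), c(1, 1), tt)
  expect_equal(max(abs(sweep(tr2$states, 2, c(1, 1)))), 0, tolerance = 1e-6)
})

test_that("integration agrees with a fixed-step explicit Euler oracle", {
  m <- rom_model(3)
  p <- c(a1 = 0.05, a2 = 0.2, a3 = 0.1, a4 = 0.3)
  y0 <- c(2, 0, 0)
  t_end <- 5
  h <- 1e-4
  y <- y0
  for (k in seq_len(t_end / h)) y <- y + h * rom_rhs(m, y, p)
  tr <- rom_integrate(m, p, y0, c(0, t_end))
  expect_equal(unname(tr$states[2, ]), unname(y), tolerance = 1e-4)
})

test_that("integration conserves weighted mass across all models", {
  set.seed(501)
  for (id in 1:8) {
    m <- rom_model(id)
    w <- mass_weights(m)
    for (rep in 1:12) {
      p <- stats::setNames(stats::runif(m$n_params, 0, 0.5), m$param_names)
      y0 <- c(stats::runif(1, 0.5, 5), rep(0, m$n_species - 1))
      tr <- rom_integrate(m, p, y0, seq(0, 50, length.out = 30))
      total <- tr$states %*% w
      expect_lt(max(abs(total - total[1])) / total[1], 1e-8)
      expect_true(all(tr$states > -1e-8))
    }
  }
})

test_that("halving solver tolerances barely moves the endpoint", {
  m <- rom_model(7)
  p <- stats::setNames(rep(c(0.05, 0.1), 3), m$param_names)
  tt <- seq(0, 100, length.out = 11)
  a <- rom_integrate(m, p, c(3, 0, 0, 0), tt, rtol = 1e-8, atol = 1e-10)
  b <- rom_integrate(m, p, c(3, 0, 0, 0), tt, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$states[11, ] - b$states[11, ])), 1e-7)
})

test_that("the generator reproduces the observation design", {
  m <- rom_model(1)
  p <- c(a1 = 0.1, a2 = 0.05)
  ds <- generate_dataset(m, p, seed = 1)
  expect_length(ds$experiments, 5)
  expect_equal(vapply(ds$experiments, `[[`, numeric(1), "y0"),
               c(1, 1.4, 2, 3, 5))
  expect_length(ds$experiments[[1]]$times, 200)
  expect_equal(ds$n_obs, 5 * 200 * 2)
  # noiseless observations equal the integrated trajectories exactly
  tr <- rom_integrate(m, p, c(5, 0), ds$experiments[[5]]$times)
  expect_identical(ds$experiments[[5]]$observed[, 1], tr$states[, 1])
  # seed determinism / divergence
  n1 <- generate_dataset(m, p, noise_sd = 0.05, seed = 7)
  n2 <- generate_dataset(m, p, noise_sd = 0.05, seed = 7)
  n3 <- generate_dataset(m, p, noise_sd = 0.05, seed = 8)
  expect_identical(n1$experiments[[1]]$observed, n2$experiments[[1]]$observed)
  expect_false(identical(n1$experiments[[1]]$observed,
                         n3$experiments[[1]]$observed))
  # fibril-only masking hides every bin but the terminal one
  fo <- generate_dataset(m, p, mask = "fibril_only", seed = 1)
  expect_true(all(is.na(fo$experiments[[1]]$observed[, 1])))
  expect_false(anyNA(fo$experiments[[1]]$observed[, 2]))
  expect_equal(fo$n_obs, 5 * 200)
  expect_error(generate_dataset(m, p, n_points = 1), "n_points")
  expect_error(generate_dataset(m, p, noise_sd = -1), "noise_sd")
})

test_that("normalization scales maxima to one and inverts exactly", {
  m <- rom_model(1)
  ds <- generate_dataset(m, c(a1 = 0.1, a2 = 0.05), seed = 3,
                         noise_sd = 0.01)
  for (mode in c("per_species_max", "global_max")) {
    nd <- normalize_dataset(ds, mode)
    all_obs <- do.call(rbind, lapply(nd$experiments, `[[`, "observed"))
    if (mode == "per_species_max") {
      expect_equal(unname(apply(all_obs, 2, max)), c(1, 1))
    } else {
      expect_equal(max(all_obs), 1)
    }
    back <- denormalize_dataset(nd)
    for (i in seq_along(ds$experiments))
      expect_equal(back$experiments[[i]]$observed,
                   ds$experiments[[i]]$observed, tolerance = 1e-12)
  }
  expect_error(normalize_dataset(normalize_dataset(ds, "global_max"),
                                 "global_max"), "already")
  # all-zero series cannot be normalized
  z <- generate_dataset(m, c(a1 = 0, a2 = 0), y0 = 1, seed = 1,
                        n_points = 5)
  z$experiments[[1]]$observed[, 2] <- 0
  expect_error(normalize_dataset(z, "per_species_max"), "B4")
})

test_that("pooling a fine dataset matches the directly simulated coarse analogue", {
  # Model 2 data pooled onto Model 1 bins: with matched kinetics the pooled
  # observable is a monotone-equivalent of the coarse simulation
  m2 <- rom_model(2)
  m1 <- rom_model(1)
  p2 <- c(a1 = 0.05, a2 = 0.1, a3 = 0.05, a4 = 0.1)
  ds2 <- generate_dataset(m2, p2, y0 = 2, n_points = 50, t_end = 100,
                          seed = 1)
  pooled <- rebin_dataset(ds2, m2, m1)
  expect_identical(pooled$species, c("B1_35", "B4"))
  # monomer-equivalent mass is preserved by the pooling
  w2 <- mass_weights(m2); w1 <- mass_weights(m1)
  expect_equal(pooled$experiments[[1]]$observed %*% w1,
               ds2$experiments[[1]]$observed %*% w2,
               ignore_attr = TRUE, tolerance = 1e-12)
  # after normalization, the pooled series is monotone-equivalent to the
  # directly simulated coarse analogue: both rise monotonically to max 1
  d1 <- generate_dataset(m1, c(a1 = 0.05, a2 = 0.1), y0 = 2, n_points = 50,
                         t_end = 100, seed = 1)
  pn <- normalize_dataset(pooled, "per_species_max")
  cn <- normalize_dataset(d1, "per_species_max")
  pb4 <- pn$experiments[[1]]$observed[, "B4"]
  cb4 <- cn$experiments[[1]]$observed[, "B4"]
  expect_true(all(diff(pb4) > -1e-8))
  expect_true(all(diff(cb4) > -1e-8))
  expect_equal(max(pb4), 1)
  expect_equal(max(cb4), 1)
  expect_equal(stats::cor(pb4, cb4, method = "spearman"), 1)
})
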