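test_that("trainer gradients match finite differences", {
  m <- rom_model(2)
  for (case in list(list(lit = 0, warp = NA_real_, ic = TRUE),
                    list(lit = 0, warp = 0.15, ic = TRUE),
                    list(lit = 1, warp = NA_real_, ic = FALSE))) {
    inp <- pinn_toy_inputs(m, tau_w = case$warp, ic = case$ic)
    a <- c(0.2, 0.35, 0.15, 0.4)
    g <- pinn_toy_eval(inp, a, literal = case$lit)
    eps <- 1e-6
    # rate-parameter gradients
    num_a <- vapply(seq_along(a), function(i) {
      a2 <- a; a2[i] <- a2[i] + eps
      (pinn_toy_eval(inp, a2, literal = case$lit)$total - g$total) / eps
    }, numeric(1))
    expect_lt(max(abs(as.numeric(g$grad_params) - num_a)), 1e-5)
    # weight and bias gradients, experiment 1, all layers
    for (l in seq_along(inp$nets[[1]]$W)) {
      W <- inp$nets[[1]]$W[[l]]
      num_W <- W * 0
      for (k in seq_along(W)) {
        inp2 <- inp; inp2$nets[[1]]$W[[l]][k] <- W[k] + eps
        num_W[k] <- (pinn_toy_eval(inp2, a, literal = case$lit)$total -
                       g$total) / eps
      }
      expect_lt(max(abs(as.numeric(g$grad_W[[1]][[l]]) -
                          as.numeric(num_W))), 1e-5)
      b <- inp$nets[[1]]$b[[l]]
      num_b <- b * 0
      for (k in seq_along(b)) {
        inp2 <- inp; inp2$nets[[1]]$b[[l]][k] <- b[k] + eps
        num_b[k] <- (pinn_toy_eval(inp2, a, literal = case$lit)$total -
                       g$total) / eps
      }
      expect_lt(max(abs(as.numeric(g$grad_b[[1]][[l]]) - num_b)), 1e-5)
    }
  }
})

test_that("training configuration validates its inputs", {
  expect_error(pinn_config(epochs = 0))
  expect_error(pinn_config(learning_rate = -1))
  expect_error(pinn_config(width = 0))
  cfg <- pinn_config()
  expect_equal(cfg$hidden_layers, 3)
  expect_equal(cfg$width, 6)
  expect_equal(cfg$epochs, 35000)
  expect_equal(cfg$learning_rate, 0.001)
  expect_identical(cfg$activation, "tanh")
  expect_identical(cfg$optimizer, "adam")
  expect_identical(cfg$physics_mode, "collocation")
})

test_that("recorded losses decompose and histories span every epoch", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = c(1, 3),
                         n_points = 25, t_end = 50, seed = 5)
  w <- c(data = 2, physics = 0.5)
  fit <- fit_rom(ds, rom_model(1),
                 config = pinn_config(epochs = 300, seed = 2,
                                      loss_weights = w))
  h <- fit$history
  expect_equal(nrow(h), 300)
  expect_equal(h$total, w[[1]] * h$mse + w[[2]] * h$physics,
               tolerance = 1e-9)
  expect_true(all(is.finite(h$total)))
  expect_true(all(c("a1", "a2") %in% names(h)))
})

test_that("a single-epoch run returns finite one-row histories", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = 2,
                         n_points = 10, t_end = 20, seed = 5)
  fit <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 1, seed = 1))
  expect_equal(nrow(fit$history), 1)
  expect_true(all(is.finite(unlist(fit$history))))
  expect_true(is.finite(fit$final_mae))
})

test_that("training is deterministic under a fixed seed", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = c(1, 2),
                         n_points = 20, t_end = 50, noise_sd = 0.01, seed = 9)
  f1 <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 200, seed = 3))
  f2 <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 200, seed = 3))
  f3 <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 200, seed = 4))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$predictions, f2$predictions)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("prediction reproduces the training grid and flags extrapolation", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = c(1, 2),
                         n_points = 15, t_end = 40, seed = 9)
  fit <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 150, seed = 1))
  p <- predict(fit, experiment = 2)
  expect_equal(unname(p), unname(fit$predictions[[2]]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dim(p), c(15, 2))
  expect_warning(pe <- predict(fit, times = c(10, 60), experiment = 1),
                 "outside")
  expect_identical(attr(pe, "extrapolated"), c(FALSE, TRUE))
  expect_true(all(is.finite(pe)))
})

test_that("the surrogate fits noiseless low-order data closely", {
  # on data generated from the fitted model, the joint loss drives the
  # surrogate onto the trajectories (normalized units)
  for (id in 1:2) {
    m <- rom_model(id)
    p <- stats::setNames(rep(c(0.05, 0.1), m$n_params / 2), m$param_names)
    ds <- generate_dataset(m, p, y0 = c(1, 2, 5), n_points = 100,
                           t_end = 100, seed = id)
    ds <- normalize_dataset(ds, "per_species_max")
    fit <- fit_rom(ds, m, config = pinn_config(epochs = 35000, seed = 1))
    expect_lt(fit$final_mae, 0.01)
  }
})

test_that("alpha/beta view accompanies the learned rates", {
  ds <- make_fixture("tiny_3pt")
  fit <- fit_rom(ds, rom_model(1), config = pinn_config(epochs = 5, seed = 1))
  expect_named(fit$alpha_beta, c("alpha1", "beta1"))
  expect_equal(fit$alpha_beta[["alpha1"]], coef(fit)[["a2"]])
  expect_equal(fit$alpha_beta[["beta1"]], coef(fit)[["a1"]])
})

test_that("nonnegative mode keeps rates positive", {
  ds <- generate_dataset(rom_model(1), c(a1 = 0.1, a2 = 0.05), y0 = 2,
                         n_points = 15, t_end = 40, seed = 2)
  fit <- fit_rom(ds, rom_model(1),
                 config = pinn_config(epochs = 300, seed = 1, nonneg = TRUE))
  expect_true(all(coef(fit) > 0))
})
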