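test_that("model construction matches the eight printed architectures", {
  n_species <- c(2, 3, 3, 4, 3, 4, 4, 5)
  n_params <- c(2, 4, 4, 6, 4, 6, 6, 8)
  for (id in 1:8) {
    m <- rom_model(id)
    expect_equal(m$n_species, n_species[id])
    expect_equal(m$n_params, n_params[id])
    expect_identical(m$species$name, oracle_species[[id]])
    expect_equal(m$species$mass_weight[1], 1)
    expect_true(all(m$species$mass_weight >= 1))
    expect_identical(m$species$role[1], "monomer_bin")
    expect_identical(m$species$role[m$n_species], "fibril")
  }
  expect_equal(rom_model(1, c(c = 2))$n_params, 2)
  expect_equal(rom_model(8, c(n = 2, m = 2, s = 2, p = 2))$n_params, 8)
})

test_that("invalid model ids and orders are rejected", {
  expect_error(rom_model(9), "model_id")
  expect_error(rom_model(0), "model_id")
  expect_error(rom_model(NA), "model_id")
  expect_error(rom_model(2, c(n = 0.5)), "order 'n'")
  expect_error(rom_model(1, list(c = -1)), "order 'c'")
})

test_that("rhs reproduces hand-derived values for Model 1", {
  m <- rom_model(1, c(c = 2))
  # zero state
  expect_equal(unname(rom_rhs(m, c(0, 0), c(a1 = 2, a2 = 3))), c(0, 0))
  # detailed balance: a1*B4 = a2*B1_35^c
  expect_equal(unname(rom_rhs(m, c(B1_35 = 1, B4 = 1), c(a1 = 1, a2 = 1))),
               c(0, 0))
  # direct substitution into the printed equations
  expect_equal(unname(rom_rhs(m, c(B1_35 = 2, B4 = 0), c(a1 = 0, a2 = 1))),
               c(-8, 4))
})

test_that("rhs agrees with the literal-equation oracles on random inputs", {
  set.seed(401)
  for (id in 1:8) {
    m <- rom_model(id)
    o <- oracle_orders[[id]]
    for (rep in 1:100) {
      st <- stats::setNames(stats::runif(m$n_species, 0, 5),
                            oracle_species[[id]])
      p <- random_params(m)
      expect_equal(unname(rom_rhs(m, st, p)),
                   unname(oracle_rhs[[id]](st, p, o)),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs validates dimensions and fractional powers of negatives", {
  m <- rom_model(1)
  expect_error(rom_rhs(m, c(1, 2, 3), c(a1 = 1, a2 = 1)), "length")
  expect_error(rom_rhs(m, c(1, 0), c(a1 = 1)), "missing rate")
  m15 <- rom_model(1, c(c = 1.5))
  expect_error(rom_rhs(m15, c(-1, 0), c(a1 = 1, a2 = 1)), "fractional")
})

test_that("mass weights annihilate the rhs for all models", {
  set.seed(402)
  expect_equal(unname(mass_weights(rom_model(1, c(c = 2)))), c(1, 2))
  expect_equal(unname(mass_weights(rom_model(8))), c(1, 2, 4, 8, 16))
  for (id in 1:8) {
    # non-default, asymmetric orders exercise the cumulative products
    m <- rom_model(id, c(n = 3, m = 2, s = 4, c = 3, p = 2))
    w <- mass_weights(m)
    expect_equal(unname(w[1]), 1)
    expect_true(all(w > 0))
    for (rep in 1:20) {
      st <- stats::runif(m$n_species, 0, 4)
      p <- random_params(m)
      d <- rom_rhs(m, st, p)
      expect_lt(abs(sum(w * d)) / max(sum(abs(w * d) + 1e-30), 1e-10), 1e-10)
    }
  }
})

test_that("no flux leaves an empty bin under nonnegative rates", {
  set.seed(403)
  for (id in 1:8) {
    m <- rom_model(id)
    for (rep in 1:25) {
      st <- stats::runif(m$n_species, 0, 3)
      empty <- sample(m$n_species, 1)
      st[empty] <- 0
      d <- rom_rhs(m, st, random_params(m))
      expect_gte(d[empty], 0)
    }
  }
})

test_that("the reduction lattice has the expected structure", {
  lat <- rom_lattice()
  expect_setequal(lattice_successors(1), c(2, 3, 5))
  expect_length(lattice_successors(8), 0)
  # every refinement adds exactly one species
  for (i in seq_len(nrow(lat$edges))) {
    expect_equal(rom_model(lat$edges$to[i])$n_species,
                 rom_model(lat$edges$from[i])$n_species + 1)
  }
  # all successors of model 1 have exactly 3 species
  expect_true(all(vapply(lattice_successors(1),
                         function(id) rom_model(id)$n_species,
                         numeric(1)) == 3))
  # enumerate all paths 1 -> 8: each has length 3 (edges)
  paths <- list(c(1))
  done <- list()
  while (length(paths)) {
    p <- paths[[1]]; paths <- paths[-1]
    succ <- lattice_successors(p[length(p)])
    if (!length(succ)) done <- c(done, list(p))
    else for (s in succ) paths <- c(paths, list(c(p, s)))
  }
  expect_true(all(vapply(done, function(p)
    p[length(p)] == 8 && length(p) == 4, logical(1))))
  # edge labels split into primary (pre-nucleation) and secondary
  expect_setequal(unique(lat$edges$label), c("primary", "secondary"))
  expect_identical(
    lat$edges$label[lat$edges$from == 1 & lat$edges$to == 3], "secondary")
  expect_identical(
    lat$edges$label[lat$edges$from == 1 & lat$edges$to == 2], "primary")
})

test_that("collapse pools fine bins in monomer equivalents", {
  m2 <- rom_model(2)  # n = m = 2
  m1 <- rom_model(1)  # c = 2
  states <- matrix(c(1, 0.5, 0.25,
                     2, 1, 0), 2, 3, byrow = TRUE)
  out <- collapse_trajectory(states, m2, m1)
  # B1_35 = (1*B1 + 2*B1_7) / 1 ; B4 = 4*B4_fine / 2
  expect_equal(out[, "B1_35"], c(1 + 2 * 0.5, 2 + 2 * 1))
  expect_equal(out[, "B4"], c(4 * 0.25 / 2, 0))
  # identity collapse
  expect_identical(collapse_trajectory(states, m2, m2), states)
  # conservation of monomer-equivalent mass for a full 8 -> 1 collapse
  set.seed(404)
  m8 <- rom_model(8)
  tr <- matrix(stats::runif(50 * 5, 0, 2), 50, 5)
  pooled <- collapse_trajectory(tr, m8, m1)
  expect_equal(pooled %*% mass_weights(m1), tr %*% mass_weights(m8),
               ignore_attr = TRUE, tolerance = 1e-12)
  # non-comparable pair: no lattice path 2 -> 6
  expect_error(collapse_trajectory(matrix(0, 2, 4), rom_model(6), rom_model(2)),
               "lattice")
})

test_that("alpha/beta view maps even rates to alpha and odd to beta", {
  ab <- alpha_beta(c(a1 = 0.1, a2 = 0.2, a3 = 0.3, a4 = 0.4))
  expect_equal(ab, c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 0.4, beta2 = 0.3))
})
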