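test_that("lattice generation places units row-major with stable geometry", {
  u <- generate_lattice(2, spacing = 1)
  expect_equal(n_units(u), 4L)
  expect_equal(unname(unit_coords(u)),
               rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))

  u14 <- generate_lattice(14, spacing = 10)
  expect_equal(n_units(u14), 196L)
  expect_equal(as.numeric(dist(unit_coords(u14)[1:2, ])), 10)

  expect_identical(unit_coords(generate_lattice(20)),
                   unit_coords(generate_lattice(20)))
  expect_error(generate_lattice(1), "n_side")
})

test_that("SAR covariate generator is seeded and honours rho", {
  lw <- lattice_weights(15)
  # rho = 0 reduces exactly to the raw normal draw
  x0 <- generate_autocorrelated_covariate(lw$W, 0, seed = 5)
  set.seed(5)
  expect_identical(x0, rnorm(225))

  x_hi <- generate_autocorrelated_covariate(lw$W, 0.7, seed = 9)
  x_lo <- generate_autocorrelated_covariate(lw$W, 0.2, seed = 9)
  expect_gt(global_moran(x_hi, lw$W)$I, global_moran(x_lo, lw$W)$I)

  expect_identical(x_hi, generate_autocorrelated_covariate(lw$W, 0.7, seed = 9))
  expect_error(generate_autocorrelated_covariate(lw$W, 1.2, seed = 1), "rho")
})

test_that("rho = 0.7 covariates are detectably clustered across seeds", {
  lw <- lattice_weights(15)
  hits <- 0L
  for (s in 1:100) {
    x <- generate_autocorrelated_covariate(lw$W, 0.7, seed = s)
    p <- global_moran(x, lw$W, n_permutations = 99, seed = s)$p_permutation
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("simulated counts recover closed-form NB moments at large n", {
  u <- generate_lattice(100)  # 10,000 units
  near_pois <- simulate_gwnbr_counts(
    u, list(`(Intercept)` = surface_constant(log(16))), alpha = 1e-8, seed = 2)
  y <- near_pois$units$crashes
  expect_true(all(y >= 0 & y == round(y)))
  expect_lt(abs(mean(y) - 16) / 16, 0.02)
  expect_gt(var(y) / mean(y), 0.95)
  expect_lt(var(y) / mean(y), 1.1)

  od <- simulate_gwnbr_counts(
    u, list(`(Intercept)` = surface_constant(log(16))), alpha = 1, seed = 2)
  expect_lt(abs(var(od$units$crashes) - 272) / 272, 0.10)
})

test_that("seed determinism gives bit-identical studies", {
  a <- simulate_preset("paper_like", seed = 4)
  b <- simulate_preset("paper_like", seed = 4)
  expect_identical(a$units$crashes, b$units$crashes)
  expect_identical(a$true_beta, b$true_beta)
  expect_identical(a$true_alpha, b$true_alpha)
})

test_that("paper-like preset is overdispersed with zonal-crash-scale counts", {
  st <- simulate_preset("paper_like", seed = 3)
  y <- st$units$crashes
  expect_equal(n_units(st$units), 196L)
  expect_true(all(y >= 0 & y == round(y)))
  expect_gt(var(y), mean(y))
  expect_gt(mean(y), 8); expect_lt(mean(y), 30)
  # maxima on the order of the largest zonal counts (hundreds, not thousands)
  expect_gt(max(y), 50); expect_lt(max(y), 600)
  expect_true(all(st$true_alpha > 0))
  expect_equal(dim(st$true_beta), c(196L, 4L))
})

test_that("gradient coefficient surfaces carry positive spatial signal", {
  lw <- lattice_weights(10)
  b <- surface_gradient(0.2, 0.8, axis = "x")(unit_coords(lw$units)[, 1],
                                              unit_coords(lw$units)[, 2])
  expect_gt(global_moran(b, lw$W)$I, 0.5)
})

test_that("simulation guards reject bad inputs", {
  u <- generate_lattice(3)
  expect_error(simulate_gwnbr_counts(u, list(`(Intercept)` = 1), alpha = -1),
               "alpha")
  expect_error(simulate_gwnbr_counts(u, list(`(Intercept)` = 40)), "overflow")
  expect_error(simulate_gwnbr_counts(u, list(`(Intercept)` = 1, zz = 0.5)),
               "zz")
})
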