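make_units <- function(df) spatial_units(cbind(df, x = seq_len(nrow(df)), y = 0))

test_that("intercept-only Poisson recovers log(ybar) and the offset identity", {
  u <- make_units(data.frame(cnt = c(3L, 8L, 15L, 4L, 9L, 11L)))
  f0 <- fit_poisson(u, cnt ~ 1)
  expect_equal(unname(f0$beta), log(mean(u$cnt)), tolerance = 1e-9)

  f_off <- fit_poisson(u, cnt ~ 1, offset = rep(log(2), 6))
  expect_equal(unname(f_off$beta), log(mean(u$cnt)) - log(2), tolerance = 1e-9)
})

test_that("Poisson recovers simulated coefficients within 3 SE", {
  set.seed(10)
  n <- 5000
  x1 <- rnorm(n)
  mu <- exp(log(16) + 0.5 * x1)
  u <- make_units(data.frame(cnt = rpois(n, mu), x1 = x1))
  f <- fit_poisson(u, cnt ~ x1)
  est <- f$coefficients
  expect_lt(abs(est$estimate[1] - log(16)) / est$se[1], 3)
  expect_lt(abs(est$estimate[2] - 0.5) / est$se[2], 3)
  expect_error(fit_poisson(make_units(data.frame(cnt = c(1.5, 2, 3))), cnt ~ 1),
               "integer")
})

test_that("NB collapses to Poisson at the alpha boundary", {
  # underdispersed counts (binomial thinning) force alpha to its lower bound
  set.seed(6)
  n <- 2000
  x1 <- rnorm(n)
  y <- rbinom(n, size = 60, prob = pmin(exp(2 + 0.3 * x1) / 60, 1))
  u <- make_units(data.frame(cnt = y, x1 = x1))
  fp <- fit_poisson(u, cnt ~ x1)
  fn <- fit_negbin(u, cnt ~ x1)
  expect_true(fn$boundary)
  expect_lt(max(abs(fn$beta - fp$beta)), 1e-4)
  # with alpha clamped at its 1e-8 floor (not exactly 0), the NB likelihood
  # sits below the Poisson one by O(alpha_min * sum(y^2)), not machine zero
  expect_gte(fn$log_likelihood, fp$log_likelihood - 1e-3)
  # the boundary alpha costs at most its own AIC penalty
  expect_lte(fp$aic, fn$aic + 2 + 1e-2)

  # near-Poisson simulated counts: estimates agree even if alpha-hat is
  # interior but tiny
  st <- simulate_preset("constant", seed = 6, n_side = 45, alpha = 1e-8)
  fp2 <- fit_poisson(st$units, crashes ~ 1)
  fn2 <- fit_negbin(st$units, crashes ~ 1)
  expect_lt(max(abs(fn2$beta - fp2$beta)), 1e-4)
  expect_lt(fn2$alpha, 1e-2)
})

test_that("NB beats Poisson on overdispersed data and satisfies ML dominance", {
  st <- simulate_preset("constant", seed = 7, n_side = 40, alpha = 1)
  fp <- fit_poisson(st$units, crashes ~ 1)
  fn <- fit_negbin(st$units, crashes ~ 1)
  expect_gte(fn$log_likelihood, fp$log_likelihood - 1e-8)
  expect_lt(fn$aic, fp$aic)
  expect_gt(fn$alpha, 0.8); expect_lt(fn$alpha, 1.2)
})

test_that("NB score equations hold at the optimum", {
  st <- simulate_preset("paper_like", seed = 8)
  fn <- fit_negbin(st$units, crashes ~ x1 + x2 + x3)
  y <- st$units$crashes
  mu <- fn$fitted_mu
  score <- crossprod(fn$X, (y - mu) / (1 + fn$alpha * mu))
  expect_lt(max(abs(score)), 1e-5)
})

test_that("NB maximum matches independent optimizers on seeded datasets", {
  skip_if_not_installed("MASS")
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    x1 <- rnorm(n)
    mu <- exp(1.8 + 0.5 * x1)
    al <- 0.7
    y <- rpois(n, rgamma(n, shape = 1 / al, rate = 1 / (al * mu)))
    u <- make_units(data.frame(cnt = y, x1 = x1))
    fn <- fit_negbin(u, cnt ~ x1)

    # general-purpose optimizer over (beta, log alpha)
    nll <- function(th) {
      m <- exp(th[1] + th[2] * x1); a <- exp(th[3])
      -sum(dnbinom(y, size = 1 / a, mu = m, log = TRUE))
    }
    opt <- optim(c(fn$beta, log(fn$alpha)) + 0.05, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_lt(abs(fn$log_likelihood - (-opt$value)), 1e-6)

    # MASS reference (theta = 1/alpha parameterization)
    mf <- MASS::glm.nb(cnt ~ x1, data = as.data.frame(u),
                       control = glm.control(epsilon = 1e-12, maxit = 100))
    expect_lt(abs(fn$log_likelihood - as.numeric(logLik(mf))), 1e-6)
    expect_lt(max(abs(fn$beta - coef(mf))), 1e-4)
  }
})

test_that("OLS baseline has closed-form estimates and Gaussian likelihood", {
  u <- make_units(data.frame(resp = c(4, 9, 2, 7, 5)))
  f0 <- fit_ols(u, resp ~ 1)
  expect_equal(unname(f0$beta), mean(u$resp))

  set.seed(11)
  df <- data.frame(x1 = rnorm(30))
  df$resp <- 2 + 3 * df$x1            # exact linear relation
  u <- make_units(df)
  fx <- fit_ols(u, resp ~ x1)
  expect_equal(max(abs(u$resp - fx$fitted_mu)), 0, tolerance = 1e-10)

  set.seed(12)
  df$resp <- 2 + 3 * df$x1 + rnorm(30)
  u <- make_units(df)
  fy <- fit_ols(u, resp ~ x1)
  n <- 30
  s2 <- sum((u$resp - fy$fitted_mu)^2) / n
  expect_equal(fy$log_likelihood, -n / 2 * (log(2 * pi * s2) + 1))
  # independent oracle: stats::logLik on the same lm
  expect_equal(fy$log_likelihood,
               as.numeric(logLik(lm(resp ~ x1, data = as.data.frame(u)))))
  dup <- u; dup$x2 <- dup$x1
  expect_error(fit_ols(dup, resp ~ x1 + x2), "rank")
})

test_that("Pearson dispersion separates equi- from overdispersed fits", {
  st <- simulate_preset("constant", seed = 13, n_side = 40, alpha = 1)
  fp <- fit_poisson(st$units, crashes ~ 1)
  expect_gt(dispersion_statistic(fp), 5)
  fn <- fit_negbin(st$units, crashes ~ 1)
  d <- dispersion_statistic(fn)
  expect_gt(d, 0.8); expect_lt(d, 1.2)
})
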