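test_that("local log-likelihood reduces to known closed forms", {
  fx <- nb_fixture()
  # all weights 1: equals the unweighted NB2 log-likelihood
  ll_w1 <- local_loglikelihood(fx$X, fx$y, rep(1, 30), fx$beta, fx$alpha)
  expect_equal(ll_w1, nb_loglik_oracle(fx$y, fx$mu, fx$alpha), tolerance = 1e-10)

  # single unit with y = 0: the gamma terms cancel to -(1/alpha) log(1 + alpha mu)
  X1 <- matrix(1, 1, 1); mu1 <- exp(0.7)
  ll0 <- local_loglikelihood(X1, 0, 1, 0.7, 0.5)
  expect_equal(ll0, -(1 / 0.5) * log1p(0.5 * mu1), tolerance = 1e-12)

  expect_error(local_loglikelihood(fx$X, fx$y, fx$w, fx$beta, -1), "alpha")
  expect_error(local_loglikelihood(fx$X, fx$y, fx$w, c(800, 0, 0), 0.5),
               "non-finite")
})

test_that("local fits with uniform weights equal the global NB fit", {
  st <- simulate_preset("paper_like", seed = 9)
  fn <- fit_negbin(st$units, crashes ~ x1 + x2)
  d <- model.matrix(~ x1 + x2, as.data.frame(st$units))
  loc <- fit_local(d, st$units$crashes, w = rep(1, 196))
  expect_lt(max(abs(loc$beta - fn$beta)), 1e-6)
  expect_lt(abs(loc$alpha - fn$alpha), 1e-6)
  expect_lt(abs(loc$loglik - fn$log_likelihood), 1e-6)
})

test_that("local fitting is monotone ascent from the warm start", {
  fx <- nb_fixture(seed = 21)
  start <- c(1, 0, 0)
  ll_start <- local_loglikelihood(fx$X, fx$y, fx$w, start, 1)
  loc <- fit_local(fx$X, fx$y, fx$w, start = start)
  expect_gte(loc$loglik, ll_start - 1e-10)
  expect_true(loc$converged)
})

test_that("under-identified local fits are rejected", {
  fx <- nb_fixture()
  w <- rep(0, 30); w[1:4] <- 1          # p + 2 = 5 positive weights required
  expect_error(fit_local(fx$X, fx$y, w), "locally unidentified")
})

test_that("golden-section search matches closed forms and a grid oracle", {
  gs <- golden_section_search(function(b) (b - 100)^2, 10, 197, integer = TRUE)
  expect_equal(gs$optimum, 100)

  mono <- golden_section_search(function(b) -b, 10, 197, integer = TRUE)
  expect_equal(mono$optimum, 197)

  for (f in list(function(b) (b - 77)^2, function(b) abs(b - 50) + 3,
                 function(b) (b - 120)^2 / 50 + 2)) {
    gs <- golden_section_search(f, 10, 197, integer = TRUE)
    grid <- vapply(10:197, f, numeric(1))
    expect_equal(gs$optimum, (10:197)[which.min(grid)])
    expect_lte(gs$score, min(gs$evaluated$score))
  }

  cont <- golden_section_search(function(b) (b - 0.3)^2, 0, 1, tol = 1e-8)
  expect_equal(cont$optimum, 0.3, tolerance = 1e-6)
  expect_error(golden_section_search(function(b) NaN, 1, 10, integer = TRUE),
               "non-finite")
})

test_that("wide-kernel GWNBR reproduces the global NB fit", {
  st <- simulate_preset("paper_like", seed = 9)
  fn <- fit_negbin(st$units, crashes ~ x1 + x2 + x3)
  gw <- fit_gwnbr(st$units, crashes ~ x1 + x2 + x3, kernel_spec("uniform"))
  rel <- abs(sweep(gw$local_beta, 2, fn$beta)) / (abs(fn$beta) + 1e-8)
  expect_lt(max(rel), 1e-4)
  expect_lt(max(abs(gw$local_alpha - fn$alpha)), 1e-4)
})

test_that("effective parameters shrink as the bandwidth widens", {
  st <- simulate_preset("gradient", seed = 14, n_side = 10)
  fits <- lapply(c(20, 50, 100),
                 function(b) fit_gwnbr(st$units, crashes ~ x1,
                                       kernel_spec("adaptive_bisquare", b)))
  ep <- vapply(fits, function(f) f$effective_params, numeric(1))
  expect_gt(ep[1], ep[2])
  expect_gt(ep[2], ep[3])
  p <- ncol(fits[[1]]$local_beta)
  expect_true(all(ep >= p & ep <= 100 * p))
})

test_that("local coefficient recovery on a constant surface stays near truth", {
  st <- simulate_preset("gradient", seed = 15, n_side = 10)
  # x2's true coefficient is constant at 0.3
  gw <- fit_gwnbr(st$units, crashes ~ x1 + x2,
                  kernel_spec("adaptive_bisquare", 60))
  z <- abs(gw$local_beta[, "x2"] - 0.3) / gw$local_se[, "x2"]
  expect_gte(mean(z < 3), 0.9)
})

test_that("bandwidth selection tracks the spatial structure of the data", {
  st_var <- simulate_preset("gradient", seed = 16, n_side = 10)
  bw_var <- select_bandwidth(st_var$units, crashes ~ x1 + x2, criterion = "aic")
  expect_lt(bw_var$optimum, 100)

  st_const <- simulate_preset("constant", seed = 16, n_side = 10, alpha = 0.5)
  bw_const <- select_bandwidth(st_const$units, crashes ~ 1, criterion = "aic")
  expect_gte(bw_const$optimum, 90)   # within 10% of the upper bound n = 100

  expect_equal(bw_var$criterion, "aic")
  expect_lte(bw_var$score, min(bw_var$evaluated$score))
})

test_that("CV criterion runs leave-one-out and may differ from AIC", {
  st <- simulate_preset("gradient", seed = 17, n_side = 8)
  bw_cv <- select_bandwidth(st$units, crashes ~ x1, criterion = "cv",
                            bounds = c(10, 64))
  expect_equal(bw_cv$criterion, "cv")
  expect_true(bw_cv$optimum >= 10 && bw_cv$optimum <= 64)
  expect_true(all(is.finite(bw_cv$evaluated$score)))
})

test_that("the local summary uses the five-number reporting format", {
  st <- simulate_preset("gradient", seed = 18, n_side = 8)
  gw <- fit_gwnbr(st$units, crashes ~ x1, kernel_spec("adaptive_bisquare", 40))
  sm <- summary(gw)
  expect_true(all(c("term", "min", "lq", "median", "uq", "max",
                    "pct_significant") %in% names(sm$coefficients)))
  cf <- sm$coefficients
  expect_true(all(cf$min <= cf$lq & cf$lq <= cf$median &
                    cf$median <= cf$uq & cf$uq <= cf$max))
  expect_true(all(gw$local_alpha > 0, na.rm = TRUE))
})

test_that("global-alpha mode holds the dispersion fixed across space", {
  st <- simulate_preset("gradient", seed = 19, n_side = 8)
  gw <- fit_gwnbr(st$units, crashes ~ x1,
                  kernel_spec("adaptive_bisquare", 40), global_alpha = TRUE)
  expect_equal(length(unique(round(gw$local_alpha, 12))), 1L)
})
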