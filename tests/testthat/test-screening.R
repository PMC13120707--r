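test_that("orthogonal centered columns have VIF exactly 1", {
  X <- poly(1:50, 3)            # orthonormal, centered columns
  colnames(X) <- c("a", "b", "c")
  v <- compute_vif(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)
})

test_that("near-duplicated columns blow VIF up as 1/(1-R^2)", {
  set.seed(1)
  x1 <- rnorm(200)
  X <- cbind(a = x1, b = x1 + rnorm(200, sd = 1e-6))
  v <- compute_vif(X)
  expect_gt(v[["a"]], 1e6)
  expect_gt(v[["b"]], 1e6)
  # oracle: VIF must match a direct lm R^2 computation
  r2 <- summary(lm(X[, 1] ~ X[, 2]))$r.squared
  expect_equal(v[["a"]], 1 / (1 - r2), tolerance = 1e-3)
})

test_that("equicorrelated triplets approach the analytic VIF of 1.5", {
  set.seed(2)
  n <- 20000
  L <- chol(matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  X <- matrix(rnorm(3 * n), n, 3) %*% L
  colnames(X) <- c("a", "b", "c")
  # analytic: R^2 = 2 rho^2 / (1 + rho) = 1/3, VIF = 1.5
  expect_equal(unname(compute_vif(X)), rep(1.5, 3), tolerance = 0.05)
})

test_that("VIF is invariant to column rescaling", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] * 0.8 + X[, 2] * 0.3
  v1 <- compute_vif(X)
  X2 <- sweep(X, 2, c(100, 1e-3, 7), "*")
  expect_equal(compute_vif(X2), v1, tolerance = 1e-8)
})

test_that("one-shot screening drops exactly the initial offenders", {
  set.seed(4)
  z <- rnorm(300)
  X <- data.frame(clean = rnorm(300),
                  hi1 = z + rnorm(300, sd = 0.1),
                  hi2 = z + rnorm(300, sd = 0.1))
  rep1 <- vif_screen(X, threshold = 10, strategy = "one_shot")
  expect_setequal(rep1$excluded$variable, c("hi1", "hi2"))
  expect_equal(rep1$retained, "clean")
  expect_true(all(rep1$excluded$reason == "vif_gt_threshold"))
  expect_true(all(rep1$vif[rep1$excluded$variable] > 10))

  # all below threshold: nothing excluded
  rep2 <- vif_screen(X[c("clean", "hi1")], threshold = 10)
  expect_equal(nrow(rep2$excluded), 0L)
  expect_setequal(rep2$retained, c("clean", "hi1"))
})

test_that("iterative screening keeps one of a duplicated pair", {
  set.seed(5)
  x <- rnorm(100)
  X <- data.frame(a = x, b = x, c = rnorm(100))
  rep_it <- vif_screen(X, threshold = 10, strategy = "iterative")
  expect_equal(sum(c("a", "b") %in% rep_it$retained), 1L)
  expect_true("c" %in% rep_it$retained)
  expect_lte(length(rep_it$history), ncol(X) + 1L)
})

test_that("excluding every variable is an error, not an empty report", {
  set.seed(6)
  x <- rnorm(50)
  X <- data.frame(a = x, b = x + rnorm(50, sd = 1e-8))
  expect_error(vif_screen(X, threshold = 10, strategy = "one_shot"),
               "empty model")
})

test_that("Moran screen flags unstructured covariates and keeps gradients", {
  lw <- lattice_weights(10)
  u <- lw$units
  flags <- 0L
  for (s in 1:100) {
    set.seed(s)
    u$noise <- rnorm(100)
    sc <- suppressWarnings(moran_screen(u, "noise", lw$W, alpha = 0.05))
    flags <- flags + ("noise" %in% sc$flagged)
  }
  expect_gte(flags, 90L)

  u$grad <- unit_coords(u)[, 1]
  sc <- moran_screen(u, "grad", lw$W)
  expect_lt(sc$moran$p, 0.001)
  expect_equal(sc$retained, "grad")

  # advisory by default, strict mode excludes
  set.seed(1); u$noise <- rnorm(100)
  expect_warning(moran_screen(u, "noise", lw$W), "advisory")
  strict <- suppressWarnings(moran_screen(u, "noise", lw$W, strict = TRUE))
  if ("noise" %in% strict$flagged) {
    expect_true("noise" %in% strict$excluded$variable)
  }

  empty <- moran_screen(u, character(0), lw$W)
  expect_equal(nrow(empty$moran), 0L)
  expect_length(empty$retained, 0L)
})

test_that("combined screen reports table columns in conventional order", {
  st <- simulate_preset("paper_like", seed = 5)
  lw <- list(W = row_standardize(contiguity_weights(st$units, "queen")))
  sc <- suppressWarnings(
    screen_variables(st$units, c("x1", "x2", "x3"), lw$W))
  expect_true(all(c("variable", "I", "expected_I", "z", "p", "vif",
                    "decision") %in% names(sc$table)))
  expect_setequal(c(sc$retained, sc$excluded$variable), c("x1", "x2", "x3"))
})
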