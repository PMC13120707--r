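test_that("2x2 lattice contiguity matches hand enumeration", {
  u <- generate_lattice(2)
  Wq <- contiguity_weights(u, "queen")
  expect_equal(unname(Matrix::rowSums(Wq$W > 0)), rep(3, 4))
  expect_true(Matrix::isSymmetric(Wq$W))

  Wr <- contiguity_weights(u, "rook")
  expect_equal(unname(Matrix::rowSums(Wr$W > 0)), rep(2, 4))
  # corner-only pairs (diagonals) excluded under rook
  expect_equal(Wr$W[1, 4], 0)
  expect_equal(Wr$W[2, 3], 0)
})

test_that("a lone polygon is an island with an all-zero row", {
  u1 <- subset_units(generate_lattice(2), 1)
  expect_warning(W <- contiguity_weights(u1, "queen"), "island")
  expect_equal(dim(W$W), c(1L, 1L))
  expect_equal(sum(W$W), 0)
})

test_that("row standardization divides rows by their sums and is idempotent", {
  W <- spatial_weights(rbind(c(0, 1, 1, 1),
                             c(1, 0, 0, 0),
                             c(0, 0, 0, 0),
                             c(1, 1, 0, 0)))
  Ws <- row_standardize(W)
  expect_equal(as.numeric(Ws$W[1, ]), c(0, 1, 1, 1) / 3)
  expect_equal(as.numeric(Ws$W[3, ]), rep(0, 4))   # empty row stays empty, no NaN
  expect_true(all(is.finite(as.matrix(Ws$W))))
  Ws2 <- row_standardize(Ws)
  expect_equal(as.matrix(Ws2$W), as.matrix(Ws$W))
})

test_that("adaptive bisquare kernel has the documented endpoints and shape", {
  # units on a line at x = 0, 1, 2, 3: with N_k = 3 the bandwidth is b = 2
  u <- spatial_units(data.frame(unit_id = 1:4, x = 0:3, y = 0))
  w <- kernel_weight_vector(u, 1, kernel_spec("adaptive_bisquare", 3))
  expect_equal(w[1], 1)                  # d = 0
  expect_equal(w[2], (1 - 0.25)^2)       # d = b/2 -> 0.5625
  expect_equal(w[3], 0)                  # d = b exactly
  expect_equal(w[4], 0)                  # beyond b
})

test_that("kernel weights are monotone non-increasing in distance", {
  u <- generate_lattice(5)
  d <- as.matrix(dist(unit_coords(u)))[13, ]
  for (spec in list(kernel_spec("adaptive_bisquare", 12),
                    kernel_spec("fixed_gaussian", 2.5))) {
    w <- kernel_weight_vector(u, 13, spec)
    ord <- order(d)
    expect_true(all(diff(w[ord]) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("adaptive kernel reaches N_k nearest units and guards its inputs", {
  u <- generate_lattice(5)
  w <- kernel_weight_vector(u, 13, kernel_spec("adaptive_bisquare", 25))
  # with N_k = n, only units exactly at distance b get zero weight
  d <- as.matrix(dist(unit_coords(u)))[13, ]
  b <- max(d)
  expect_true(all((w > 0) == (d < b)))

  # in generic position (no distance ties) at least N_k - 1 weights are
  # positive; lattice ties at the bandwidth radius legitimately drop out
  set.seed(30)
  ug <- spatial_units(data.frame(unit_id = 1:40, x = runif(40), y = runif(40)))
  for (nk in c(5, 20, 40)) {
    wg <- kernel_weight_vector(ug, 7, kernel_spec("adaptive_bisquare", nk))
    expect_gte(sum(wg > 0), nk - 1)
  }

  expect_error(kernel_weight_vector(u, 13, kernel_spec("adaptive_bisquare", 26)),
               "exceeds")
  dup <- spatial_units(data.frame(unit_id = 1:3, x = c(0, 0, 1), y = 0))
  expect_error(kernel_weight_vector(dup, 1, kernel_spec("adaptive_bisquare", 2)),
               "duplicate")
})

test_that("knn weights link each unit to exactly k neighbors", {
  u <- generate_lattice(4)
  W <- knn_weights(u, k = 3)
  expect_equal(unname(Matrix::rowSums(W$W > 0)), rep(3, 16))
  expect_equal(unname(Matrix::diag(W$W)), rep(0, 16))
})

test_that("edge-list export and import round-trips the matrix", {
  lw <- lattice_weights(3, standardize = TRUE)
  el <- weights_to_edgelist(lw$W)
  expect_named(el, c("i_id", "j_id", "weight"))
  W2 <- edgelist_to_weights(el, ids = lw$W$ids, style = "row_standardized")
  expect_equal(as.matrix(W2$W), as.matrix(lw$W$W))
})

test_that("weight matrix validity contracts are enforced", {
  expect_error(spatial_weights(matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(spatial_weights(matrix(c(0, -1, 0, 0), 2)), "nonnegative")
  M <- matrix(c(0, 0.4, 1, 0), 2)
  expect_error(spatial_weights(M, style = "row_standardized"), "sum to 1")
})
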