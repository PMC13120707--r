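# shared fixtures: everything is generated in code, nothing read from disk

lattice_weights <- function(n_side, rule = "rook", standardize = TRUE) {
  u <- generate_lattice(n_side)
  W <- suppressWarnings(contiguity_weights(u, rule))
  if (standardize) W <- row_standardize(W)
  list(units = u, W = W)
}

# small NB fixture with known design, used by likelihood-oracle tests
nb_fixture <- function(n = 30, seed = 42) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(1.5, 0.4, -0.3)
  mu <- exp(drop(X %*% beta))
  alpha <- 0.6
  y <- rpois(n, rgamma(n, shape = 1 / alpha, rate = 1 / (alpha * mu)))
  w <- runif(n)
  list(X = X, y = y, w = w, beta = beta, alpha = alpha, mu = mu)
}

# independent NB2 log-pmf oracle built on dnbinom (size = 1/alpha)
nb_loglik_oracle <- function(y, mu, alpha, w = NULL) {
  ll <- dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)
  if (is.null(w)) sum(ll) else sum(w * ll)
}
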