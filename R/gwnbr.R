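#' Local weighted NB2 log-likelihood
#'
#' The geographically weighted negative binomial log-likelihood around one
#' focal location: each unit j contributes its NB2 log-density at
#' `mu_j = t_j exp(x_j' beta)` and dispersion `alpha`, multiplied by its
#' kernel weight `w_j`. All gamma functions are evaluated through `lgamma`.
#'
#' @param X Design matrix (n x p, including the intercept column).
#' @param y Nonnegative integer counts (length n).
#' @param w Kernel weights in `[0, 1]` (length n).
#' @param beta Coefficient vector (length p).
#' @param alpha Positive dispersion.
#' @param offset Optional log-exposure vector (default 0).
#' @return The weighted log-likelihood (a single number).
#' @export
local_loglikelihood <- function(X, y, w, beta, alpha, offset = NULL) {
  X <- as.matrix(X)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  off <- offset %||% rep(0, nrow(X))
  mu <- exp(off + drop(X %*% beta))
  bad <- which(!is.finite(mu) | mu <= 0)
  if (length(bad)) {
    stop(sprintf("non-finite mean at unit %d (mu = %g)", bad[1], mu[bad[1]]),
         call. = FALSE)
  }
  ll <- nb_logdens(y, mu, alpha)
  if (any(!is.finite(ll[w > 0]))) {
    bad <- which(!is.finite(ll) & w > 0)[1]
    stop(sprintf("non-finite log-likelihood term at unit %d (mu = %g)",
                 bad, mu[bad]), call. = FALSE)
  }
  sum(w * ll)
}

#' Fit one local weighted NB model
#'
#' The inner estimator of GWNBR at a single focal location: iteratively
#' reweighted least squares for `beta`,
#' `beta_hat = (X' W A X)^{-1} X' W A z` with `A = diag(mu / (1 + alpha mu))`
#' and adjusted response `z = X beta + (y - mu)/mu` (offset removed),
#' alternated with safeguarded one-dimensional profile maximization of the
#' local log-likelihood over `alpha`, until the weighted log-likelihood
#' stabilizes. The kernel weights `W` stay fixed throughout.
#'
#' @inheritParams local_loglikelihood
#' @param start Optional warm-start coefficient vector (e.g. the global NB
#'   estimate).
#' @param fixed_alpha If supplied, `alpha` is held at this value (global-alpha
#'   mode) and only `beta` is estimated.
#' @param control List: `max_outer` (default 100), `tol` (default 1e-8),
#'   `alpha_bounds` (default `c(1e-8, 1e4)`).
#' @return List with `beta`, `alpha`, `covariance` (`(X'WAX)^{-1}` at
#'   convergence), `loglik`, `converged`, `iterations`.
#' @export
fit_local <- function(X, y, w, offset = NULL, start = NULL, fixed_alpha = NULL,
                      control = list()) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(w > 0) < p + 2) {
    stop(sprintf("locally unidentified: only %d units with positive weight for %d parameters",
                 sum(w > 0), p), call. = FALSE)
  }
  ctrl <- modifyList(list(max_outer = 100, tol = 1e-8,
                          alpha_bounds = c(1e-8, 1e4)), control)
  off <- offset %||% rep(0, nrow(X))
  act <- which(w > 0)
  fit <- nb_fit(X[act, , drop = FALSE], y[act], off[act], w = w[act],
                beta_start = start, fixed_alpha = fixed_alpha,
                max_outer = ctrl$max_outer, tol = ctrl$tol,
                alpha_bounds = ctrl$alpha_bounds)
  if (isTRUE(fit$singular)) {
    stop("locally unidentified: singular weighted information matrix",
         call. = FALSE)
  }
  covb <- solve(fit$XtWA)
  dimnames(covb) <- list(colnames(X), colnames(X))
  names(fit$beta) <- colnames(X)
  list(beta = fit$beta, alpha = fit$alpha, covariance = covb,
       loglik = fit$loglik, converged = fit$converged,
       boundary = fit$boundary, iterations = fit$iterations)
}

#' Geographically weighted negative binomial regression
#'
#' Fits the NB2 model `y_j ~ NB(t_j exp(sum_k beta_k(u_j, v_j) x_jk),
#' alpha(u_j, v_j))` by running a kernel-weighted local NB fit (see
#' [fit_local()]) at every unit's centroid. By default the dispersion is
#' estimated locally along with the coefficients; `global_alpha = TRUE` holds
#' it at the global NB estimate. Every local fit is warm-started from the
#' global NB coefficients.
#'
#' The fitted mean at unit i uses unit i's own local coefficients; the model
#' log-likelihood is the unweighted sum of NB log-densities at those local
#' fits; AIC uses the effective number of parameters `tr(S) + d`, where the
#' i-th row of the hat-like matrix S is
#' `x_i' (X' W_i A_i X)^{-1} X' W_i A_i`, and `d` counts the dispersion:
#' 1 when alpha is global, `tr(S)/p` when alpha varies locally (its surface
#' is as flexible as one coefficient surface; both collapse to 1 in the
#' wide-kernel limit).
#'
#' @inheritParams fit_poisson
#' @param kernel A [kernel_spec()]; adaptive bandwidths must lie in
#'   `[p + 2, n]`.
#' @param global_alpha Hold the dispersion global instead of local.
#' @param control Passed to the local fits, see [fit_local()].
#' @return A `gwnbr_fit`: per-unit coefficient matrix `local_beta`, local
#'   dispersions, standard errors, t-statistics, fitted means, effective
#'   parameters, log-likelihood, AIC, per-unit convergence flags.
#' @seealso [select_bandwidth()], [summary.gwnbr_fit()]
#' @export
fit_gwnbr <- function(units, formula, kernel, offset = NULL,
                      global_alpha = FALSE, control = list()) {
  stopifnot(inherits(kernel, "kernel_spec"))
  d <- build_design(units, formula, offset)
  y <- check_count_response(d$y)
  X <- d$X
  n <- nrow(X); p <- ncol(X)
  if (kernel$kind == "adaptive_bisquare" &&
      (kernel$bandwidth < p + 2 || kernel$bandwidth > n)) {
    stop(sprintf("adaptive bandwidth must lie in [%d, %d]", p + 2, n),
         call. = FALSE)
  }

  glob <- nb_fit(X, y, d$offset)
  alpha_fix <- if (global_alpha) glob$alpha else NULL
  D <- euclid_dist(unit_coords(units))
  ids <- unit_ids(units)

  local_beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  local_se <- local_beta
  local_alpha <- rep(NA_real_, n)
  fitted_mu <- rep(NA_real_, n)
  s_ii <- rep(NA_real_, n)
  conv <- rep(NA, n)
  failures <- character(0)

  for (i in seq_len(n)) {
    w <- kernel_weights_from_dist(D[i, ], kernel, ids = ids)
    res <- tryCatch(
      fit_local(X, y, w, offset = d$offset, start = glob$beta,
                fixed_alpha = alpha_fix, control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("unit %s: %s", ids[i],
                                      conditionMessage(res)))
      next
    }
    local_beta[i, ] <- res$beta
    local_se[i, ] <- sqrt(diag(res$covariance))
    local_alpha[i] <- res$alpha
    conv[i] <- res$converged
    mu_i <- exp(d$offset[i] + sum(X[i, ] * res$beta))
    fitted_mu[i] <- mu_i
    a_i <- mu_i / (1 + res$alpha * mu_i)
    s_ii[i] <- drop(t(X[i, ]) %*% res$covariance %*% X[i, ]) * a_i  # w_ii = 1
  }

  if (length(failures) > 0.1 * n) {
    stop(sprintf("GWNBR aborted: %d of %d local fits failed\n%s",
                 length(failures), n,
                 paste(utils::head(failures, 10), collapse = "\n")), call. = FALSE)
  }
  ok <- !is.na(local_alpha)
  # dispersion complexity: one parameter when alpha is global; when alpha
  # varies locally its surface is as flexible as one coefficient surface,
  # so it contributes tr(S)/p effective parameters (this collapses to +1 in
  # the wide-kernel limit, matching the global NB parameter count)
  tr_s <- sum(s_ii[ok])
  eff_p <- tr_s + if (global_alpha) 1 else tr_s / p
  loglik <- sum(nb_logdens(y[ok], fitted_mu[ok], local_alpha[ok]))
  aic <- -2 * loglik + 2 * eff_p

  structure(list(local_beta = local_beta, local_alpha = local_alpha,
                 local_se = local_se,
                 local_tstat = local_beta / local_se,
                 fitted_mu = fitted_mu, kernel = kernel,
                 effective_params = eff_p, global_loglik = loglik, aic = aic,
                 per_unit_convergence = conv, failures = failures,
                 global_alpha = global_alpha,
                 global_fit = list(beta = glob$beta, alpha = glob$alpha),
                 y = y, X = X, offset = d$offset, formula = formula,
                 ids = ids, coords = unit_coords(units)),
            class = "gwnbr_fit")
}

#' @export
#' @method print gwnbr_fit
print.gwnbr_fit <- function(x, ...) {
  cat(sprintf("<gwnbr_fit> %d units, kernel %s (bandwidth %s), %s alpha\n",
              length(x$y), x$kernel$kind, format(x$kernel$bandwidth),
              if (x$global_alpha) "global" else "local"))
  cat(sprintf("  logLik = %.3f, effective params = %.2f, AIC = %.3f\n",
              x$global_loglik, x$effective_params, x$aic))
  if (length(x$failures)) cat(sprintf("  %d local fits failed\n", length(x$failures)))
  print(summary(x)$coefficients, row.names = FALSE)
  invisible(x)
}

#' Five-number summary of local GWNBR estimates
#'
#' Summarizes each term's local coefficient distribution by its minimum,
#' lower quartile, median, upper quartile and maximum — the conventional
#' reporting format for geographically weighted models — along with the
#' share of units where the local t-statistic is significant at
#' `sig_level` (two-sided normal reference, no multiplicity correction).
#'
#' @param object A `gwnbr_fit`.
#' @param sig_level Two-sided significance level for the local t-statistics.
#' @param ... Unused.
#' @return A list with `coefficients` (data.frame: term, min, lq, median,
#'   uq, max, pct_significant), `alpha` (the same five numbers for the local
#'   dispersion), `aic`, `effective_params`.
#' @export
#' @method summary gwnbr_fit
summary.gwnbr_fit <- function(object, sig_level = 0.05, ...) {
  zcrit <- qnorm(1 - sig_level / 2)
  terms <- colnames(object$local_beta)
  rows <- lapply(terms, function(tm) {
    b <- object$local_beta[, tm]
    fn <- five_num(b[!is.na(b)])
    t_ <- object$local_tstat[, tm]
    data.frame(term = tm, min = fn$min, lq = fn$lq, median = fn$median,
               uq = fn$uq, max = fn$max,
               pct_significant = 100 * mean(abs(t_) > zcrit, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  a <- object$local_alpha[!is.na(object$local_alpha)]
  out <- list(coefficients = do.call(rbind, rows),
              alpha = as.data.frame(five_num(a)),
              aic = object$aic, effective_params = object$effective_params,
              sig_level = sig_level)
  class(out) <- "summary.gwnbr_fit"
  out
}

#' @export
#' @method print summary.gwnbr_fit
print.summary.gwnbr_fit <- function(x, ...) {
  cat(sprintf("Local coefficient summary (AIC %.3f, effective params %.2f)\n",
              x$aic, x$effective_params))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat("Local dispersion alpha:\n")
  print(format(x$alpha, digits = 4), row.names = FALSE)
  invisible(x)
}

# leave-one-out CV score at one bandwidth: each unit predicted from a local
# fit in which its own kernel weight is forced to zero
gwnbr_cv_score <- function(units, formula, kernel, offset = NULL,
                           global_alpha = FALSE, control = list()) {
  d <- build_design(units, formula, offset)
  y <- check_count_response(d$y)
  X <- d$X
  n <- nrow(X)
  glob <- nb_fit(X, y, d$offset)
  alpha_fix <- if (global_alpha) glob$alpha else NULL
  D <- euclid_dist(unit_coords(units))
  ids <- unit_ids(units)
  sse <- 0
  for (i in seq_len(n)) {
    w <- kernel_weights_from_dist(D[i, ], kernel, ids = ids)
    w[i] <- 0
    res <- tryCatch(
      fit_local(X, y, w, offset = d$offset, start = glob$beta,
                fixed_alpha = alpha_fix, control = control),
      error = function(e) e)
    if (inherits(res, "error")) return(Inf)
    mu_i <- exp(d$offset[i] + sum(X[i, ] * res$beta))
    sse <- sse + (y[i] - mu_i)^2
  }
  sse
}

#' Golden-section search
#'
#' Derivative-free minimization of a unimodal scalar objective on `[lo, hi]`.
#' In integer mode (adaptive bandwidths are neighbor counts) probes are
#' rounded to integers, the interval is narrowed until at most a handful of
#' candidates remain, those are evaluated exhaustively, and the best
#' evaluated integer is returned. The interval endpoints are always probed,
#' so monotone objectives return a boundary optimum. All evaluations are
#' cached and reported.
#'
#' @param objective Function of one numeric argument returning a finite
#'   score (lower is better).
#' @param lo,hi Search bounds, `lo < hi`.
#' @param tol Termination width for continuous search.
#' @param integer Round probes to integers and terminate exactly.
#' @return A `bandwidth_search`: list with `optimum`, `score`, `evaluated`
#'   (data.frame of bandwidth/score in evaluation order), `bounds`, `tol`.
#' @export
golden_section_search <- function(objective, lo, hi, tol = 1e-6,
                                  integer = FALSE) {
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  hist_b <- numeric(0); hist_s <- numeric(0)
  n_bad <- 0L
  f <- function(b) {
    if (integer) b <- round(b)
    key <- format(b, digits = 15)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(b)
    if (!is.finite(v)) { n_bad <<- n_bad + 1L; v <- Inf }
    cache[[key]] <- v
    hist_b <<- c(hist_b, b); hist_s <<- c(hist_s, v)
    v
  }

  invphi <- (sqrt(5) - 1) / 2
  f(lo); f(hi)
  a <- lo; b <- hi
  x1 <- b - invphi * (b - a); x2 <- a + invphi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  width_stop <- if (integer) 2.5 else tol
  while ((b - a) > width_stop) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - invphi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + invphi * (b - a); f2 <- f(x2)
    }
  }
  if (integer) for (bb in seq(ceiling(a - 1e-9), floor(b + 1e-9))) f(bb)

  n_tot <- length(hist_b)
  if (n_bad > 0.5 * n_tot) {
    stop("bandwidth search aborted: objective non-finite at more than half the probes\n",
         paste(sprintf("  b = %g -> %g", hist_b, hist_s), collapse = "\n"),
         call. = FALSE)
  }
  best <- which.min(hist_s)
  structure(list(optimum = hist_b[best], score = hist_s[best],
                 evaluated = data.frame(bandwidth = hist_b, score = hist_s),
                 bounds = c(lo, hi), tol = tol, integer = integer,
                 criterion = NULL),
            class = "bandwidth_search")
}

#' @export
#' @method print bandwidth_search
print.bandwidth_search <- function(x, ...) {
  cat(sprintf("Bandwidth search (%s): optimum %s with score %.4f (%d evaluations)\n",
              x$criterion %||% "custom", format(x$optimum), x$score,
              nrow(x$evaluated)))
  invisible(x)
}

#' Data-driven GWNBR bandwidth selection
#'
#' Golden-section search for the kernel bandwidth minimizing either the
#' GWNBR AIC or the leave-one-out cross-validation score
#' `CV(b) = sum_i (y_i - yhat_(i)(b))^2`, where `yhat_(i)` is unit i's
#' fitted mean from a local fit with its own kernel weight forced to zero.
#' For adaptive kernels the bandwidth is an integer neighbor count searched
#' exactly; default bounds are `[max(p + 2, ceil(0.1 n)), n]`.
#'
#' AIC- and CV-selected bandwidths can legitimately differ; fitting and
#' reporting both is standard practice.
#'
#' @inheritParams fit_gwnbr
#' @param kernel_kind `"adaptive_bisquare"` or `"fixed_gaussian"`.
#' @param criterion `"aic"` or `"cv"`.
#' @param bounds Length-2 search bounds (neighbor counts or distances).
#' @param tol Termination width for fixed (continuous) bandwidth search.
#' @return A `bandwidth_search` (see [golden_section_search()]) with
#'   `criterion` filled in.
#' @export
select_bandwidth <- function(units, formula,
                             kernel_kind = c("adaptive_bisquare", "fixed_gaussian"),
                             criterion = c("aic", "cv"), bounds = NULL,
                             tol = NULL, offset = NULL, global_alpha = FALSE,
                             control = list()) {
  kernel_kind <- match.arg(kernel_kind)
  criterion <- match.arg(criterion)
  d <- build_design(units, formula, offset)
  n <- nrow(d$X); p <- ncol(d$X)
  adaptive <- kernel_kind == "adaptive_bisquare"
  if (is.null(bounds)) {
    bounds <- if (adaptive) c(max(p + 2, ceiling(0.1 * n)), n) else {
      D <- euclid_dist(unit_coords(units))
      c(max(apply(D + diag(Inf, n), 1, min)), max(D))
    }
  }
  if (adaptive && (bounds[1] < p + 2 || bounds[2] > n)) {
    stop(sprintf("adaptive bounds must lie within [%d, %d]", p + 2, n),
         call. = FALSE)
  }
  obj <- function(b) {
    spec <- kernel_spec(kernel_kind, b)
    if (criterion == "aic") {
      fit <- tryCatch(fit_gwnbr(units, formula, spec, offset = offset,
                                global_alpha = global_alpha, control = control),
                      error = function(e) NULL)
      if (is.null(fit)) Inf else fit$aic
    } else {
      gwnbr_cv_score(units, formula, spec, offset = offset,
                     global_alpha = global_alpha, control = control)
    }
  }
  res <- golden_section_search(obj, bounds[1], bounds[2],
                               tol = tol %||% if (adaptive) 1 else 1e-2,
                               integer = adaptive)
  res$criterion <- criterion
  res
}
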