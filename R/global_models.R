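# ---- shared NB2 internals -------------------------------------------------
# NB2: Var(y) = mu + alpha * mu^2, log link. All likelihoods via lgamma.

nb_logdens <- function(y, mu, alpha) {
  r <- 1 / alpha
  lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
    y * log(alpha * mu) - (y + r) * log1p(alpha * mu)
}

nb_wloglik <- function(y, mu, alpha, w = NULL) {
  ll <- nb_logdens(y, mu, alpha)
  if (is.null(w)) sum(ll) else sum(w * ll)
}

# profile maximization of the weighted NB log-likelihood over log(alpha)
nb_profile_alpha <- function(y, mu, w = NULL, lower = 1e-8, upper = 1e4) {
  f <- function(la) nb_wloglik(y, mu, exp(la), w)
  opt <- optimize(f, c(log(lower), log(upper)), maximum = TRUE, tol = 1e-9)
  a_hat <- exp(opt$maximum)
  # safeguard the boundaries: optimize() never probes the endpoints
  ll_lo <- f(log(lower))
  if (ll_lo >= opt$objective) return(list(alpha = lower, loglik = ll_lo,
                                          boundary = TRUE))
  list(alpha = a_hat, loglik = opt$objective, boundary = a_hat <= lower * 1.01)
}

# IRLS for beta given alpha, with kernel weights w and step-halving so the
# weighted log-likelihood never decreases
nb_irls_beta <- function(X, y, offset, w, alpha, beta,
                         max_iter = 50, tol = 1e-10) {
  eta <- offset + drop(X %*% beta)
  mu <- exp(eta)
  ll <- nb_wloglik(y, mu, alpha, w)
  for (it in seq_len(max_iter)) {
    a <- mu / (1 + alpha * mu)            # GLM IRLS weight for NB2, log link
    z <- (eta - offset) + (y - mu) / mu   # adjusted response (offset removed)
    wa <- w * a
    XtWA <- crossprod(X, wa * X)
    beta_new <- tryCatch(drop(solve(XtWA, crossprod(X, wa * z))),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      return(list(beta = beta, loglik = ll, converged = FALSE,
                  singular = TRUE, iterations = it, XtWA = XtWA))
    }
    step <- beta_new - beta
    lam <- 1
    repeat {
      cand <- beta + lam * step
      eta_c <- offset + drop(X %*% cand)
      mu_c <- exp(eta_c)
      ll_c <- if (all(is.finite(mu_c)) && all(mu_c > 0)) {
        nb_wloglik(y, mu_c, alpha, w)
      } else -Inf
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; eta_c <- eta; mu_c <- mu; ll_c <- ll; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c; mu <- mu_c
    # primary criterion is the score equation; the log-likelihood stall and
    # step-size checks only catch step-halved dead ends
    sc <- max(abs(crossprod(X, w * (y - mu) / (1 + alpha * mu))))
    converged <- sc < 1e-8 || moved < 1e-12 ||
      ((ll_c - ll) < tol * (abs(ll) + 1) && sc < 1e-7)
    ll <- ll_c
    if (converged) {
      a <- mu / (1 + alpha * mu)
      return(list(beta = beta, loglik = ll, converged = TRUE, singular = FALSE,
                  iterations = it, XtWA = crossprod(X, (w * a) * X),
                  mu = mu, a = a))
    }
  }
  a <- mu / (1 + alpha * mu)
  list(beta = beta, loglik = ll, converged = FALSE, singular = FALSE,
       iterations = max_iter, XtWA = crossprod(X, (w * a) * X), mu = mu, a = a)
}

# joint (beta, alpha) weighted NB fit: alternate IRLS and alpha profile
nb_fit <- function(X, y, offset, w = NULL, beta_start = NULL, alpha_start = NULL,
                   fixed_alpha = NULL, max_outer = 100, tol = 1e-8,
                   alpha_bounds = c(1e-8, 1e4)) {
  n <- length(y); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(beta_start)) {
    # Poisson start via a few IRLS passes at alpha ~ 0
    beta_start <- rep(0, p)
    ybar <- weighted.mean(pmax(y, 0.5), w)
    if ("(Intercept)" %in% colnames(X)) {
      beta_start[match("(Intercept)", colnames(X))] <- log(ybar) - mean(offset)
    }
    beta_start <- nb_irls_beta(X, y, offset, w, 1e-8, beta_start)$beta
  }
  beta <- beta_start
  if (!is.null(fixed_alpha)) {
    fit <- nb_irls_beta(X, y, offset, w, fixed_alpha, beta)
    return(list(beta = fit$beta, alpha = fixed_alpha, loglik = fit$loglik,
                converged = fit$converged, singular = isTRUE(fit$singular),
                boundary = FALSE, iterations = fit$iterations,
                XtWA = fit$XtWA, mu = fit$mu, a = fit$a))
  }

  mu <- exp(offset + drop(X %*% beta))
  alpha <- alpha_start %||% {
    # moment start: Pearson-type estimate of excess dispersion
    num <- sum(w * ((y - mu)^2 - mu)) ; den <- sum(w * mu^2)
    max(min(num / max(den, 1e-12), 100), 1e-3)
  }
  ll_old <- -Inf
  converged <- FALSE; singular <- FALSE; it <- 0L
  fit <- NULL
  for (it in seq_len(max_outer)) {
    fit <- nb_irls_beta(X, y, offset, w, alpha, beta)
    if (isTRUE(fit$singular)) { singular <- TRUE; break }
    beta <- fit$beta
    mu <- exp(offset + drop(X %*% beta))
    prof <- nb_profile_alpha(y, mu, w, alpha_bounds[1], alpha_bounds[2])
    alpha <- prof$alpha
    ll <- prof$loglik
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  final <- nb_irls_beta(X, y, offset, w, alpha, beta, max_iter = 100)
  list(beta = final$beta, alpha = alpha, loglik = final$loglik,
       converged = converged && final$converged, singular = singular,
       boundary = alpha <= alpha_bounds[1] * 1.01,
       iterations = it, XtWA = final$XtWA, mu = final$mu, a = final$a)
}

# ---- model frame helper ---------------------------------------------------

build_design <- function(units, formula, offset = NULL) {
  mf <- model.frame(formula, data = as.data.frame(units), na.action = NULL)
  if (anyNA(mf)) stop("missing values in model variables; clean the table first",
                      call. = FALSE)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  off <- if (is.null(offset)) rep(0, nrow(X)) else {
    if (is.character(offset)) {
      t_j <- as.numeric(units[[offset]])
      if (is.null(t_j)) stop("offset column not found: ", offset, call. = FALSE)
      if (any(t_j <= 0)) stop("offset (exposure) must be positive", call. = FALSE)
      log(t_j)
    } else {
      if (length(offset) != nrow(X)) stop("offset length mismatch", call. = FALSE)
      as.numeric(offset)
    }
  }
  list(y = y, X = X, offset = off)
}

new_count_fit <- function(family, beta, se, alpha, loglik, mu, n_params,
                          converged, n_iter, y, X, offset, formula,
                          boundary = FALSE) {
  est <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se),
                    statistic = unname(beta / se),
                    p = 2 * pnorm(-abs(unname(beta / se))),
                    stringsAsFactors = FALSE)
  structure(list(family = family, coefficients = est, beta = beta,
                 alpha = alpha, log_likelihood = loglik, fitted_mu = mu,
                 n_params = n_params, converged = converged,
                 n_iterations = n_iter, boundary = boundary,
                 y = y, X = X, offset = offset, formula = formula,
                 aic = -2 * loglik + 2 * n_params),
            class = "count_fit")
}

#' @export
#' @method print count_fit
print.count_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<count_fit> family = %s, n = %d, logLik = %.3f, AIC = %.3f\n",
              x$family, length(x$y), x$log_likelihood, x$aic))
  if (!is.null(x$alpha)) {
    cat(sprintf("  dispersion alpha = %.4g%s\n", x$alpha,
                if (isTRUE(x$boundary)) " (at lower boundary)" else ""))
  }
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

# ---- exported fitters -----------------------------------------------------

#' Global Poisson regression
#'
#' Maximum-likelihood Poisson GLM with log link,
#' `ln mu = ln t + X beta`, fitted by IRLS (via [stats::glm()]) to tight
#' tolerance. The equidispersion baseline of the model-comparison ladder.
#'
#' @param units A [spatial_units()] object.
#' @param formula Model formula, e.g. `crashes ~ x1 + x2`.
#' @param offset Optional exposure: a column name (logged internally) or a
#'   numeric vector already on the log scale.
#' @return A `count_fit` with coefficient table, log-likelihood, fitted
#'   means, and convergence information.
#' @export
fit_poisson <- function(units, formula, offset = NULL) {
  d <- build_design(units, formula, offset)
  y <- check_count_response(d$y)
  if (qr(d$X)$rank < ncol(d$X)) stop("design matrix is rank deficient", call. = FALSE)
  fit <- glm.fit(d$X, y, family = poisson(), offset = d$offset,
                 control = list(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop(sprintf("Poisson IRLS failed to converge after %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  beta <- coef(fit)
  mu <- fit$fitted.values
  info <- crossprod(d$X, mu * d$X)
  se <- sqrt(diag(solve(info)))
  ll <- sum(dpois(y, mu, log = TRUE))
  new_count_fit("poisson", beta, se, NULL, ll, mu, ncol(d$X), TRUE, fit$iter,
                y, d$X, d$offset, formula)
}

#' Global negative binomial (NB2) regression
#'
#' Joint maximum likelihood over `(beta, alpha)` for the NB2 model with
#' `Var(y) = mu + alpha mu^2` and log link: weighted IRLS updates of `beta`
#' alternate with safeguarded one-dimensional maximization of the profile
#' log-likelihood over `alpha` on `[1e-8, 1e4]` until the joint
#' log-likelihood stabilizes. Underdispersed data drive `alpha` to the lower
#' bound, which is reported with a boundary flag (the Poisson limit).
#'
#' Standard errors come from the information matrix `X' A X` at the optimum,
#' with `A = diag(mu / (1 + alpha mu))`.
#'
#' @inheritParams fit_poisson
#' @param control List: `max_outer` (default 100), `alpha_bounds`.
#' @return A `count_fit` with `alpha` filled in; `n_params` counts the
#'   regression coefficients plus one for `alpha`.
#' @export
fit_negbin <- function(units, formula, offset = NULL, control = list()) {
  d <- build_design(units, formula, offset)
  y <- check_count_response(d$y)
  if (qr(d$X)$rank < ncol(d$X)) stop("design matrix is rank deficient", call. = FALSE)
  ctrl <- modifyList(list(max_outer = 100, alpha_bounds = c(1e-8, 1e4)), control)
  pois <- fit_poisson(units, formula, offset)
  fit <- nb_fit(d$X, y, d$offset, beta_start = pois$beta,
                max_outer = ctrl$max_outer, alpha_bounds = ctrl$alpha_bounds)
  if (isTRUE(fit$singular)) stop("NB IRLS hit a singular information matrix",
                                 call. = FALSE)
  se <- sqrt(diag(solve(fit$XtWA)))
  names(fit$beta) <- colnames(d$X)
  new_count_fit("negbin", fit$beta, se, fit$alpha, fit$loglik, fit$mu,
                ncol(d$X) + 1L, fit$converged, fit$iterations,
                y, d$X, d$offset, formula, boundary = fit$boundary)
}

#' Global ordinary least squares baseline
#'
#' Least-squares fit with the Gaussian maximum-likelihood log-likelihood
#' `-n/2 (log(2 pi sigma2_hat) + 1)` (with `sigma2_hat = RSS/n`) so its AIC
#' is defined on the same likelihood scale as the count models' in
#' comparison tables.
#'
#' @inheritParams fit_poisson
#' @return A `count_fit` with family `"ols"`; `n_params` counts the
#'   coefficients plus one for the error variance.
#' @export
fit_ols <- function(units, formula) {
  d <- build_design(units, formula)
  y <- as.numeric(d$y)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    dep <- colnames(d$X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(d$X, y)
  beta <- coef(fit)
  res <- fit$residuals
  n <- length(y)
  sigma2_hat <- sum(res^2) / n
  ll <- -n / 2 * (log(2 * pi * sigma2_hat) + 1)
  s2_unbiased <- sum(res^2) / (n - ncol(d$X))
  se <- sqrt(diag(chol2inv(qr.R(qrX)) * s2_unbiased))
  names(se) <- colnames(d$X)
  new_count_fit("ols", beta, se, NULL, ll, fit$fitted.values,
                ncol(d$X) + 1L, TRUE, 1L, y, d$X, rep(0, n), formula)
}

#' Pearson dispersion statistic
#'
#' `chi^2 / df`: the Pearson chi-square `sum (y - mu)^2 / V(mu)` divided by
#' the residual degrees of freedom `n - k`, with `V(mu) = mu` for Poisson and
#' `mu + alpha mu^2` for the negative binomial. Values well above 1 on a
#' Poisson fit indicate overdispersion.
#'
#' @param fit A `count_fit` from [fit_poisson()] or [fit_negbin()].
#' @return A single number.
#' @export
dispersion_statistic <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  if (!fit$family %in% c("poisson", "negbin")) {
    stop("dispersion statistic is defined for count families", call. = FALSE)
  }
  n <- length(fit$y); k <- fit$n_params
  if (n <= k) stop("no residual degrees of freedom", call. = FALSE)
  v <- if (fit$family == "poisson") fit$fitted_mu else
    fit$fitted_mu + fit$alpha * fit$fitted_mu^2
  sum((fit$y - fit$fitted_mu)^2 / v) / (n - k)
}
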