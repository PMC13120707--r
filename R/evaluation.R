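#' Model fit metrics: AIC, MAD, RMSE
#'
#' `AIC = -2 loglik + 2 k`, `MAD = mean(|yhat - y|)`,
#' `RMSE = sqrt(mean((yhat - y)^2))`. RMSE is always at least MAD
#' (quadratic mean vs arithmetic mean), which is asserted on every call.
#'
#' @param y Observed counts.
#' @param y_hat Fitted values (same length).
#' @param loglik Maximized log-likelihood.
#' @param k Parameter count (may be a non-integer effective count).
#' @param label Model label carried into comparison tables.
#' @return An object of class `fit_metrics` with fields `label`,
#'   `log_likelihood`, `k`, `aic`, `mad`, `rmse`.
#' @examples
#' compute_metrics(c(0, 3), c(1, 1), loglik = 0, k = 2)
#' @export
compute_metrics <- function(y, y_hat, loglik, k, label = "model") {
  if (length(y) != length(y_hat)) stop("y and y_hat length mismatch", call. = FALSE)
  if (length(y) < 1) stop("empty data", call. = FALSE)
  if (k < 0) stop("k must be nonnegative", call. = FALSE)
  mad_ <- sum(abs(y_hat - y)) / length(y)
  rmse_ <- sqrt(sum((y_hat - y)^2) / length(y))
  stopifnot(rmse_ >= mad_ - 1e-12)
  structure(list(label = label, log_likelihood = loglik, k = k,
                 aic = -2 * loglik + 2 * k, mad = mad_, rmse = rmse_),
            class = "fit_metrics")
}

#' @export
#' @method print fit_metrics
print.fit_metrics <- function(x, ...) {
  cat(sprintf("%s: logLik = %.3f, k = %.2f, AIC = %.3f, MAD = %.3f, RMSE = %.3f\n",
              x$label, x$log_likelihood, x$k, x$aic, x$mad, x$rmse))
  invisible(x)
}

# ---- residuals ------------------------------------------------------------

#' Residuals for global and geographically weighted count fits
#'
#' Deviance residuals (default) or Pearson residuals. For the negative
#' binomial the per-fit dispersion is used — GWNBR residuals use each unit's
#' local alpha. OLS fits return raw response residuals for both types.
#'
#' @param object A `count_fit` or `gwnbr_fit`.
#' @param type `"deviance"` or `"pearson"`.
#' @param ... Unused.
#' @return Numeric residual vector.
#' @export
residuals.count_fit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  if (object$family == "ols") return(object$y - object$fitted_mu)
  alpha <- if (object$family == "negbin") object$alpha else 0
  count_residuals(object$y, object$fitted_mu, alpha, type)
}

#' @rdname residuals.count_fit
#' @export
residuals.gwnbr_fit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  count_residuals(object$y, object$fitted_mu, object$local_alpha, type)
}

count_residuals <- function(y, mu, alpha, type) {
  if (type == "pearson") {
    return((y - mu) / sqrt(mu + alpha * mu^2))
  }
  # NB2 unit deviance; alpha -> 0 recovers the Poisson deviance
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(alpha > 1e-12,
               (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu)),
               y - mu)
  d <- pmax(2 * (t1 - t2), 0)
  sign(y - mu) * sqrt(d)
}

#' @export
fitted.count_fit <- function(object, ...) object$fitted_mu

#' @export
fitted.gwnbr_fit <- function(object, ...) object$fitted_mu

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params, class = "logLik")
}

#' @export
logLik.gwnbr_fit <- function(object, ...) {
  structure(object$global_loglik, df = object$effective_params, class = "logLik")
}

# ---- model comparison -----------------------------------------------------

model_row_info <- function(fit, label) {
  if (inherits(fit, "count_fit")) {
    list(label = label %||% toupper(fit$family),
         type = switch(fit$family, ols = "OLS", poisson = "Poisson",
                       negbin = "Negative binomial"),
         bandwidth = NA_real_, loglik = fit$log_likelihood, k = fit$n_params,
         y = fit$y, mu = fit$fitted_mu)
  } else if (inherits(fit, "gwnbr_fit")) {
    list(label = label %||% "GWNBR",
         type = sprintf("GWNBR (%s)", fit$kernel$kind),
         bandwidth = as.numeric(fit$kernel$bandwidth %||% NA),
         loglik = fit$global_loglik, k = fit$effective_params,
         y = fit$y, mu = fit$fitted_mu)
  } else stop("unsupported fit object", call. = FALSE)
}

#' Side-by-side model comparison with residual spatial diagnostics
#'
#' One row per fitted model with its log-likelihood, AIC, RMSE and MAD, plus
#' global Moran's I of the model residuals and its p-value — a well-fitting
#' spatial model should leave no significant spatial autocorrelation in its
#' residuals. All fits must be on the same response vector. The row with the
#' lowest AIC is flagged.
#'
#' @param fits Named list of `count_fit` / `gwnbr_fit` objects.
#' @param W A [spatial_weights()] object for the residual Moran tests.
#' @param residual_type `"deviance"` (default) or `"pearson"`.
#' @param n_permutations,seed Optional permutation inference for the
#'   residual Moran tests.
#' @return A data.frame of class `model_comparison` with columns `model`,
#'   `type`, `bandwidth`, `likelihood`, `aic`, `rmse`, `mad`,
#'   `residual_moran_I`, `residual_moran_p`, `best_aic`.
#' @export
compare_models <- function(fits, W, residual_type = c("deviance", "pearson"),
                           n_permutations = 0, seed = NULL) {
  residual_type <- match.arg(residual_type)
  stopifnot(inherits(W, "spatial_weights"), length(fits) >= 1)
  labels <- names(fits) %||% rep(NA_character_, length(fits))
  info <- Map(model_row_info, fits, as.list(labels))
  y0 <- info[[1]]$y
  for (fi in info) {
    if (!identical(as.numeric(fi$y), as.numeric(y0))) {
      stop("all models must be fitted to identical data", call. = FALSE)
    }
  }
  rows <- lapply(seq_along(fits), function(i) {
    fi <- info[[i]]
    m <- compute_metrics(fi$y, fi$mu, fi$loglik, fi$k, fi$label)
    r <- residuals(fits[[i]], type = residual_type)
    mt <- global_moran(r, W, n_permutations = n_permutations, seed = seed)
    data.frame(model = fi$label, type = fi$type, bandwidth = fi$bandwidth,
               likelihood = fi$loglik, aic = m$aic, rmse = m$rmse, mad = m$mad,
               residual_moran_I = mt$I,
               residual_moran_p = mt$p_permutation %||% mt$p_analytic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$best_aic <- seq_len(nrow(tab)) == which.min(tab$aic)
  structure(tab, residual_type = residual_type,
            class = c("model_comparison", "data.frame"))
}

#' @export
#' @method print model_comparison
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (%s residual Moran)\n", attr(x, "residual_type")))
  df <- as.data.frame(x)
  df$best_aic <- ifelse(df$best_aic, "*", "")
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}
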