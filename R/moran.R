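#' Global Moran's I
#'
#' The global spatial-autocorrelation statistic
#' `I = (N / W0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W0` the sum of all weights. Expectation under the null is
#' `-1/(N-1)`; the analytic variance is computed under the randomization
#' assumption by default (the normality variant is available), giving the
#' z-score `(I - E[I]) / sqrt(Var[I])`. Optionally a permutation test is run
#' by randomly relabelling the values over the units; the permutation p-value
#' counts permutations at least as extreme (two-sided around `E[I]`) and
#' includes the observed statistic in numerator and denominator so it is
#' never exactly zero.
#'
#' @param x Numeric vector, one value per unit (not constant).
#' @param W A [spatial_weights()] object with `W$n == length(x)`.
#' @param n_permutations Number of permutations (0 = analytic inference only).
#' @param seed Integer seed for the permutations.
#' @param variance `"randomization"` (default) or `"normality"`.
#' @param conf_level Confidence level for the reported critical z value.
#' @return An object of class `moran_test` with fields `I`, `expected_I`,
#'   `variance_I`, `z_score`, `p_analytic`, `p_permutation`,
#'   `n_permutations`, `variance_assumption`, `critical_value`, `n`.
#' @examples
#' units <- generate_lattice(5)
#' W <- row_standardize(contiguity_weights(units, "rook"))
#' x <- unit_coords(units)[, 1] + rnorm(25, sd = 0.1)
#' global_moran(x, W, n_permutations = 99, seed = 1)
#' @export
global_moran <- function(x, W, n_permutations = 0, seed = NULL,
                         variance = c("randomization", "normality"),
                         conf_level = 0.99) {
  variance <- match.arg(variance)
  stopifnot(inherits(W, "spatial_weights"))
  n <- W$n
  if (length(x) != n) stop("length(x) must equal the number of units", call. = FALSE)
  if (n < 3) stop("Moran's I needs at least 3 units", call. = FALSE)
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  if (var(x) == 0) stop("zero variance: x is constant", call. = FALSE)

  Wm <- W$W
  z <- x - mean(x)
  m2sum <- sum(z^2)
  S0 <- sum(Wm)
  I <- (n / S0) * as.numeric(crossprod(z, Wm %*% z)) / m2sum
  EI <- -1 / (n - 1)

  S1 <- sum((Wm + Matrix::t(Wm))^2) / 2
  S2 <- sum((Matrix::rowSums(Wm) + Matrix::colSums(Wm))^2)
  if (variance == "randomization") {
    b2 <- n * sum(z^4) / m2sum^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  } else {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  }
  zsc <- (I - EI) / sqrt(VI)
  p_an <- 2 * pnorm(-abs(zsc))

  p_perm <- NULL
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    Zp <- vapply(seq_len(n_permutations), function(k) z[sample.int(n)],
                 numeric(n))
    Ip <- (n / S0) * colSums(Zp * as.matrix(Wm %*% Zp)) / m2sum
    p_perm <- (1 + sum(abs(Ip - EI) >= abs(I - EI))) / (n_permutations + 1)
  }

  structure(list(I = I, expected_I = EI, variance_I = VI, z_score = zsc,
                 p_analytic = p_an, p_permutation = p_perm,
                 n_permutations = n_permutations,
                 variance_assumption = variance,
                 critical_value = critical_z(conf_level),
                 conf_level = conf_level, n = n),
            class = "moran_test")
}

#' @export
#' @method print moran_test
print.moran_test <- function(x, digits = 4, ...) {
  cat("Global Moran's I\n")
  cat(sprintf("  I = %.*f   E[I] = %.*f   Var[I] = %.3g (%s)\n",
              digits, x$I, digits, x$expected_I, x$variance_I,
              x$variance_assumption))
  cat(sprintf("  z = %.*f   (two-sided %.0f%% critical value %.2f)   p = %.4g\n",
              digits, x$z_score, 100 * x$conf_level, x$critical_value,
              x$p_analytic))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_permutation, x$n_permutations))
  }
  invisible(x)
}

#' Local Moran (LISA) with cluster classification
#'
#' Per-unit local Moran statistics `I_i = z_i * sum_j w_ij z_j / m2` with
#' `z` the mean-deviation of `x` and `m2 = sum(z^2)/n`, so that with
#' row-standardized weights the average of the local statistics equals global
#' Moran's I. Inference is by conditional permutation: unit i's value is held
#' fixed while its neighbors' values are drawn without replacement from the
#' remaining n-1 values. Significant units are classified by the quadrant of
#' `(z_i, lag_i)`: High-High, Low-Low (clusters, positive `I_i`), Low-High,
#' High-Low (outliers, negative `I_i`); all others are labelled `NS`.
#'
#' @inheritParams global_moran
#' @param significance_level Per-unit threshold gating the cluster labels.
#' @param fdr If `TRUE`, apply Benjamini-Hochberg correction to the local
#'   p-values before gating (off by default, matching common mapping
#'   practice).
#' @return A data.frame of class `lisa` with columns `unit_id`, `local_I`,
#'   `z_local`, `p_local`, `cluster`, and attributes `significance_level`,
#'   `global_I`.
#' @export
local_moran <- function(x, W, n_permutations = 999, seed = NULL,
                        significance_level = 0.05, fdr = FALSE) {
  stopifnot(inherits(W, "spatial_weights"))
  if (W$style != "row_standardized") {
    stop("local_moran requires row-standardized weights", call. = FALSE)
  }
  n <- W$n
  if (length(x) != n) stop("length(x) must equal the number of units", call. = FALSE)
  if (var(x) == 0) stop("zero variance: x is constant", call. = FALSE)

  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- as.numeric(W$W %*% z)
  Ii <- z * lag / m2

  p_local <- rep(NA_real_, n)
  z_local <- rep(NA_real_, n)
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    Wm <- methods::as(W$W, "TsparseMatrix")
    nb_idx <- split(Wm@j + 1L, factor(Wm@i + 1L, levels = seq_len(n)))
    nb_w <- split(Wm@x, factor(Wm@i + 1L, levels = seq_len(n)))
    for (i in seq_len(n)) {
      k <- length(nb_idx[[i]])
      if (k == 0L) next
      pool <- z[-i]
      samp <- vapply(seq_len(n_permutations),
                     function(p) pool[sample.int(n - 1L, k)],
                     numeric(k))
      lag_p <- if (k == 1L) nb_w[[i]] * samp else as.numeric(nb_w[[i]] %*% samp)
      Ip <- z[i] * lag_p / m2
      p_local[i] <- (1 + sum(abs(Ip) >= abs(Ii[i]))) / (n_permutations + 1)
      s <- sd(Ip)
      z_local[i] <- if (s > 0) (Ii[i] - mean(Ip)) / s else NA_real_
    }
  }

  p_gate <- if (fdr) p.adjust(p_local, method = "BH") else p_local
  quad <- ifelse(z > 0 & lag > 0, "HH",
                 ifelse(z < 0 & lag < 0, "LL",
                        ifelse(z < 0 & lag > 0, "LH",
                               ifelse(z > 0 & lag < 0, "HL", "NS"))))
  cluster <- ifelse(!is.na(p_gate) & p_gate < significance_level, quad, "NS")

  res <- data.frame(unit_id = W$ids, local_I = Ii, z_local = z_local,
                    p_local = p_local, cluster = cluster,
                    stringsAsFactors = FALSE)
  structure(res,
            significance_level = significance_level,
            n_permutations = n_permutations,
            global_I = mean(Ii),
            fdr = fdr,
            class = c("lisa", "data.frame"))
}

#' @export
#' @method print lisa
print.lisa <- function(x, ...) {
  cat(sprintf("Local Moran (LISA): %d units, %d permutations, significance %.3g%s\n",
              nrow(x), attr(x, "n_permutations"), attr(x, "significance_level"),
              if (isTRUE(attr(x, "fdr"))) " (FDR-adjusted)" else ""))
  print(table(cluster = x$cluster))
  invisible(x)
}
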