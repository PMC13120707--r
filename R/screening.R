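#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the least-squares
#' regression of covariate k on all other covariates plus an intercept.
#' Perfectly collinear columns get `Inf` rather than an error.
#'
#' @param X A numeric matrix or data.frame of covariates (no response), with
#'   more rows than columns + 1 and no constant column.
#' @return A named numeric vector of VIFs (all `>= 1`).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need more observations than covariates + 1", call. = FALSE)
  if (any(apply(X, 2, var) == 0)) stop("constant covariate column", call. = FALSE)
  if (p == 1L) return(setNames(1, colnames(X)))
  vif <- vapply(seq_len(p), function(k) {
    yk <- X[, k]
    fit <- lm.fit(cbind(1, X[, -k, drop = FALSE]), yk)
    r2 <- 1 - sum(fit$residuals^2) / sum((yk - mean(yk))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(vif, colnames(X))
}

#' VIF-based multicollinearity screen
#'
#' Excludes covariates whose VIF exceeds a threshold. `"one_shot"` removes
#' every offender at once, based on the initial VIFs (the conventional
#' reporting-table practice); `"iterative"` repeatedly removes the single
#' worst offender and recomputes until all remaining VIFs are at or below
#' the threshold (statistically safer when offenders are mutually collinear).
#'
#' @param X Covariate matrix or data.frame.
#' @param threshold VIF exclusion threshold (> 1); 10 is the conventional cut.
#' @param strategy `"one_shot"` (default) or `"iterative"`.
#' @return A `screening_report` with fields `vif` (initial VIFs), `retained`,
#'   `excluded` (data.frame of variable/reason), `history` (per-iteration
#'   VIFs for the iterative strategy).
#' @export
vif_screen <- function(X, threshold = 10, strategy = c("one_shot", "iterative")) {
  strategy <- match.arg(strategy)
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  X <- as.data.frame(X)
  vars <- names(X)
  vif0 <- compute_vif(X)
  history <- list(vif0)

  if (strategy == "one_shot") {
    drop <- names(vif0)[vif0 > threshold]
  } else {
    drop <- character(0)
    keep <- vars
    v <- vif0
    while (length(keep) > 1L && max(v) > threshold) {
      worst <- names(v)[which.max(v)]
      drop <- c(drop, worst)
      keep <- setdiff(keep, worst)
      if (length(keep) < 2L) break
      v <- compute_vif(X[keep])
      history <- c(history, list(v))
    }
    if (length(keep) == 1L && length(drop) && max(history[[length(history)]]) > threshold) {
      # a single remaining column has no collinearity by definition
      v <- setNames(1, keep)
    }
  }

  retained <- setdiff(vars, drop)
  if (!length(retained)) stop("empty model: all variables excluded", call. = FALSE)
  excluded <- data.frame(variable = drop,
                         reason = rep("vif_gt_threshold", length(drop)),
                         stringsAsFactors = FALSE)
  structure(list(vif = vif0, retained = retained, excluded = excluded,
                 threshold = threshold, strategy = strategy, history = history),
            class = "screening_report")
}

#' @export
#' @method print screening_report
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report (%s)\n", x$strategy %||% "moran"))
  if (!is.null(x$vif)) {
    cat("  VIF: ", paste(sprintf("%s=%.2f", names(x$vif), x$vif), collapse = ", "),
        "\n", sep = "")
  }
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(sprintf("%s (%s)", x$excluded$variable,
                                     x$excluded$reason), collapse = ", "), "\n")
  } else cat("  excluded: none\n")
  invisible(x)
}

#' Moran-based spatial-pattern screen
#'
#' Computes global Moran's I for each named variable and flags those whose
#' p-value is at or above `alpha` as lacking significant spatial pattern.
#' Advisory by default (flagged variables stay retained with a warning);
#' `strict = TRUE` moves them to the excluded list, for workflows that drop
#' spatially unstructured covariates before geographically weighted
#' modelling.
#'
#' @param units A [spatial_units()] object.
#' @param variables Character vector of covariate column names.
#' @param W A [spatial_weights()] object.
#' @param alpha Significance level for the screen.
#' @param n_permutations Permutations for the Moran test (0 = analytic p).
#' @param seed Seed for permutation inference.
#' @param strict If `TRUE`, flagged variables are excluded rather than only
#'   flagged.
#' @return A `screening_report` with a `moran` data.frame (variable, I,
#'   expected_I, z, p), `retained`, `excluded`, `flagged`.
#' @export
moran_screen <- function(units, variables, W, alpha = 0.05,
                         n_permutations = 0, seed = NULL, strict = FALSE) {
  stopifnot(inherits(units, "spatial_units"))
  if (!length(variables)) {
    return(structure(list(moran = data.frame(variable = character(0),
                                             I = numeric(0), expected_I = numeric(0),
                                             z = numeric(0), p = numeric(0)),
                          retained = character(0),
                          excluded = data.frame(variable = character(0),
                                                reason = character(0)),
                          flagged = character(0), alpha = alpha),
                     class = "screening_report"))
  }
  missing <- setdiff(variables, names(units))
  if (length(missing)) stop("unknown variable(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  rows <- lapply(variables, function(v) {
    mt <- global_moran(as.numeric(units[[v]]), W,
                       n_permutations = n_permutations, seed = seed)
    p <- mt$p_permutation %||% mt$p_analytic
    data.frame(variable = v, I = mt$I, expected_I = mt$expected_I,
               z = mt$z_score, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  flagged <- tab$variable[tab$p >= alpha]
  if (length(flagged) && !strict) {
    warning("variables without significant spatial pattern (advisory): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  excluded_vars <- if (strict) flagged else character(0)
  structure(list(moran = tab,
                 retained = setdiff(variables, excluded_vars),
                 excluded = data.frame(variable = excluded_vars,
                                       reason = rep("moran_nonsignificant",
                                                    length(excluded_vars)),
                                       stringsAsFactors = FALSE),
                 flagged = flagged, alpha = alpha),
            class = "screening_report")
}

#' Combined variable screening
#'
#' Runs the Moran spatial-pattern screen and then the VIF collinearity screen
#' on the surviving variables, mirroring the two-stage screening workflow of
#' zonal crash-frequency studies. Output columns mirror the conventional
#' reporting table (variable, Moran's I, expected index, z, p, VIF,
#' decision).
#'
#' @inheritParams moran_screen
#' @param vif_threshold VIF exclusion threshold.
#' @param strategy VIF strategy, see [vif_screen()].
#' @param strict_moran Enforce (rather than advise on) the Moran screen.
#' @return A `screening_report` with `table` (the combined per-variable
#'   report), `retained`, `excluded`.
#' @export
screen_variables <- function(units, variables, W, alpha = 0.05,
                             vif_threshold = 10,
                             strategy = c("one_shot", "iterative"),
                             strict_moran = FALSE,
                             n_permutations = 0, seed = NULL) {
  strategy <- match.arg(strategy)
  ms <- moran_screen(units, variables, W, alpha = alpha,
                     n_permutations = n_permutations, seed = seed,
                     strict = strict_moran)
  vs <- vif_screen(as.data.frame(units)[ms$retained], threshold = vif_threshold,
                   strategy = strategy)
  tab <- ms$moran
  tab$vif <- vs$vif[tab$variable]
  excluded <- rbind(ms$excluded, vs$excluded)
  tab$decision <- ifelse(tab$variable %in% excluded$variable, "excluded",
                         ifelse(tab$variable %in% ms$flagged,
                                "retained (moran advisory flag)", "retained"))
  structure(list(table = tab,
                 vif = vs$vif,
                 retained = setdiff(variables, excluded$variable),
                 excluded = excluded,
                 alpha = alpha, vif_threshold = vif_threshold,
                 strategy = strategy),
            class = "screening_report")
}
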