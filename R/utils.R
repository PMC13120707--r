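`%||%` <- function(a, b) if (is.null(a)) b else a

# counts must be nonnegative integers (stored as numeric)
check_count_response <- function(y, what = "response") {
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y))) {
    stop(what, " must be numeric and finite", call. = FALSE)
  }
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop(what, " must contain nonnegative integer counts", call. = FALSE)
  }
  round(y)
}

#' Two-sided standard-normal critical value
#'
#' The z threshold beyond which a two-sided standard-normal test rejects at
#' the given confidence level. At 99% confidence this is the familiar 2.58
#' used when reporting Moran z-scores.
#'
#' @param conf_level Confidence level in (0, 1); default 0.99.
#' @return A single positive number.
#' @examples
#' critical_z(0.99)  # 2.575829
#' @export
critical_z <- function(conf_level = 0.99) {
  stopifnot(is.numeric(conf_level), length(conf_level) == 1L,
            conf_level > 0, conf_level < 1)
  qnorm(1 - (1 - conf_level) / 2)
}

# five-number summary row used by the local-coefficient tables
five_num <- function(x) {
  q <- quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE, na.rm = TRUE)
  setNames(as.list(q), c("min", "lq", "median", "uq", "max"))
}

# pairwise Euclidean distances between planar coordinate matrices
euclid_dist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
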