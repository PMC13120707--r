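#' Spatial weight matrix
#'
#' A sparse n x n matrix of nonnegative spatial weights with a zero diagonal,
#' tagged with its standardization style and provenance. Weights quantify the
#' spatial connection between pairs of units and drive both Moran statistics
#' and simulated spatial processes.
#'
#' @param W An n x n base or Matrix matrix of nonnegative weights, zero
#'   diagonal.
#' @param ids Unit identifiers (length n).
#' @param style `"binary"` or `"row_standardized"`.
#' @param provenance Free-text origin tag, e.g. `"queen"`, `"rook"`, `"knn"`,
#'   `"inverse_distance"`.
#' @return An object of class `spatial_weights`.
#' @seealso [contiguity_weights()], [knn_weights()], [row_standardize()]
#' @export
spatial_weights <- function(W, ids = NULL,
                            style = c("binary", "row_standardized"),
                            provenance = "custom") {
  style <- match.arg(style)
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  n <- nrow(W)
  if (ncol(W) != n) stop("weight matrix must be square", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("ids must have one entry per unit", call. = FALSE)
  obj <- structure(list(W = W, ids = ids, style = style, provenance = provenance,
                        n = n),
                   class = "spatial_weights")
  validate_spatial_weights(obj)
  obj
}

validate_spatial_weights <- function(x) {
  W <- x$W
  if (any(Matrix::diag(W) != 0)) stop("weight matrix diagonal must be zero", call. = FALSE)
  v <- W@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    stop("weights must be finite and nonnegative", call. = FALSE)
  }
  if (x$style == "row_standardized") {
    rs <- Matrix::rowSums(W)
    bad <- abs(rs - 1) > 1e-12 & rs > 0
    if (any(bad)) stop("row-standardized rows must sum to 1", call. = FALSE)
  }
  invisible(x)
}

#' @export
#' @method print spatial_weights
print.spatial_weights <- function(x, ...) {
  nn <- Matrix::rowSums(x$W > 0)
  cat(sprintf("<spatial_weights> n = %d, style = %s, provenance = %s\n",
              x$n, x$style, x$provenance))
  cat(sprintf("  links: %d; neighbors per unit: min %d, mean %.2f, max %d; islands: %d\n",
              sum(nn), min(nn), mean(nn), max(nn), sum(nn == 0)))
  invisible(x)
}

#' Polygon contiguity weights
#'
#' Binary queen or rook contiguity from polygon geometry: queen neighbors
#' share at least one boundary vertex, rook neighbors share a full boundary
#' segment (edge). Vertex matching uses a snap tolerance, which assumes
#' topologically clean polygons (shared boundaries digitized with identical
#' vertices), as administrative boundary files and generated lattices are.
#'
#' @param units A [spatial_units()] object with polygon geometry.
#' @param rule `"queen"` or `"rook"`.
#' @param snap Snap tolerance for vertex matching, in coordinate units.
#' @return A binary symmetric [spatial_weights()] matrix. Units without any
#'   neighbor (islands) trigger a warning and keep an empty row.
#' @export
contiguity_weights <- function(units, rule = c("queen", "rook"), snap = 1e-8) {
  rule <- match.arg(rule)
  geoms <- unit_geometry(units)
  ids <- unit_ids(units)
  if (is.null(geoms)) stop("contiguity weights require polygon geometry", call. = FALSE)
  missing <- which(vapply(geoms, is.null, logical(1)))
  if (length(missing)) {
    stop("missing geometry for unit(s): ", paste(ids[missing], collapse = ", "),
         call. = FALSE)
  }
  n <- n_units(units)

  key_of <- function(m) paste(round(m[, 1] / snap), round(m[, 2] / snap))
  features <- lapply(seq_len(n), function(i) {
    ring <- as.matrix(geoms[[i]])
    if (isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    vk <- unique(key_of(ring))
    if (rule == "queen") return(vk)
    # rook: undirected edges as sorted vertex-key pairs
    nxt <- c(seq_len(nrow(ring))[-1], 1L)
    a <- key_of(ring); b <- a[nxt]
    unique(ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|")))
  })

  tab <- data.frame(key = unlist(features),
                    unit = rep.int(seq_len(n), lengths(features)),
                    stringsAsFactors = FALSE)
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (grp in split(tab$unit, tab$key)) {
    grp <- unique(grp)
    if (length(grp) > 1L) {
      cmb <- utils::combn(grp, 2L)
      pairs_i <- c(pairs_i, cmb[1, ]); pairs_j <- c(pairs_j, cmb[2, ])
    }
  }
  if (length(pairs_i)) {
    W <- Matrix::sparseMatrix(i = c(pairs_i, pairs_j), j = c(pairs_j, pairs_i),
                              x = 1, dims = c(n, n))
    W <- Matrix::drop0((W > 0) * 1)
  } else {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  islands <- which(Matrix::rowSums(W) == 0)
  if (length(islands)) {
    warning("island unit(s) with no neighbors: ",
            paste(ids[islands], collapse = ", "), call. = FALSE)
  }
  spatial_weights(W, ids = ids, style = "binary", provenance = rule)
}

#' k-nearest-neighbor weights
#'
#' Binary weights linking every unit to its `k` nearest units by Euclidean
#' centroid distance (the resulting matrix is generally asymmetric). The
#' default fallback for point-only data when no polygon contiguity exists.
#'
#' @param units A [spatial_units()] object.
#' @param k Number of neighbors, `1 <= k < n`.
#' @return A binary [spatial_weights()] matrix with provenance `"knn"`.
#' @export
knn_weights <- function(units, k = 8) {
  n <- n_units(units)
  if (k < 1 || k >= n) stop("k must be in [1, n-1]", call. = FALSE)
  D <- euclid_dist(unit_coords(units))
  diag(D) <- Inf
  idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.integer(t(idx)),
                            x = 1, dims = c(n, n))
  spatial_weights(W, ids = unit_ids(units), style = "binary", provenance = "knn")
}

#' Row-standardize a weight matrix
#'
#' Divides each nonempty row by its sum so rows sum to one; empty (island)
#' rows are left all-zero. Idempotent.
#'
#' @param W A [spatial_weights()] object.
#' @return A [spatial_weights()] object with style `"row_standardized"`.
#' @export
row_standardize <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  rs <- Matrix::rowSums(W$W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  Wrs <- Matrix::Diagonal(x = scale) %*% W$W
  spatial_weights(Wrs, ids = W$ids, style = "row_standardized",
                  provenance = W$provenance)
}

#' Geographic kernel specification
#'
#' Describes the distance kernel used to weight observations around each
#' regression (focal) point in GWNBR. The adaptive bisquare kernel's bandwidth
#' is a nearest-neighbor count: the kernel reaches to the focal unit's
#' `bandwidth`-th nearest unit (the focal unit itself counts, at distance 0),
#' so denser areas get tighter kernels. The fixed Gaussian kernel's bandwidth
#' is a distance. The `"uniform"` kind gives every unit weight one (the
#' global-model limit, mainly for testing).
#'
#' @param kind `"adaptive_bisquare"`, `"fixed_gaussian"` or `"uniform"`.
#' @param bandwidth Integer neighbor count (adaptive), positive distance
#'   (fixed), ignored for `"uniform"`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("adaptive_bisquare", "fixed_gaussian", "uniform"),
                        bandwidth = NULL) {
  kind <- match.arg(kind)
  if (kind == "adaptive_bisquare") {
    if (is.null(bandwidth) || bandwidth < 1 || abs(bandwidth - round(bandwidth)) > 1e-8) {
      stop("adaptive bandwidth must be a positive integer neighbor count", call. = FALSE)
    }
    bandwidth <- as.integer(round(bandwidth))
  } else if (kind == "fixed_gaussian") {
    if (is.null(bandwidth) || !is.finite(bandwidth) || bandwidth <= 0) {
      stop("fixed bandwidth must be a positive distance", call. = FALSE)
    }
  }
  structure(list(kind = kind, bandwidth = bandwidth), class = "kernel_spec")
}

#' @export
#' @method print kernel_spec
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, bandwidth = %s\n", x$kind,
              format(x$bandwidth %||% NA)))
  invisible(x)
}

# kernel weights from a precomputed focal distance vector
kernel_weights_from_dist <- function(d, spec, ids = NULL) {
  n <- length(d)
  if (spec$kind == "uniform") return(rep(1, n))
  if (spec$kind == "adaptive_bisquare") {
    nk <- spec$bandwidth
    if (nk > n) stop("adaptive bandwidth exceeds the number of units", call. = FALSE)
    b <- sort(d, partial = nk)[nk]
    if (b <= 0) {
      dup <- which(d <= 0)
      stop("zero kernel bandwidth: duplicate coordinates among units ",
           paste(if (is.null(ids)) dup else ids[dup], collapse = ", "),
           call. = FALSE)
    }
    w <- ifelse(d < b, (1 - (d / b)^2)^2, 0)
  } else {
    w <- exp(-0.5 * (d / spec$bandwidth)^2)
  }
  w[d == 0] <- 1
  w
}

#' Kernel weight vector around one focal unit
#'
#' Evaluates the geographic kernel at every unit's distance from the focal
#' unit. Adaptive bisquare: with `b` the distance from the focal unit to its
#' `N_k`-th nearest unit (focal included at distance 0), weights are
#' `(1 - (d/b)^2)^2` for `d < b` and 0 beyond; ties exactly at distance `b`
#' get weight 0. Fixed Gaussian: `exp(-0.5 (d/b)^2)`. The focal unit always
#' has weight 1.
#'
#' @param units A [spatial_units()] object.
#' @param focal Index of the focal unit (1-based row index).
#' @param spec A [kernel_spec()].
#' @return A numeric vector of weights in `[0, 1]`, one per unit.
#' @export
kernel_weight_vector <- function(units, focal, spec) {
  xy <- unit_coords(units)
  n <- nrow(xy)
  stopifnot(focal >= 1, focal <= n)
  d <- sqrt((xy[, 1] - xy[focal, 1])^2 + (xy[, 2] - xy[focal, 2])^2)
  kernel_weights_from_dist(d, spec, ids = unit_ids(units))
}

#' Weight matrix edge-list import/export
#'
#' `weights_to_edgelist` flattens a weight matrix to a three-column
#' data.frame (`i_id`, `j_id`, `weight`) with only nonzero entries;
#' `edgelist_to_weights` rebuilds the matrix.
#'
#' @param W A [spatial_weights()] object.
#' @param edges A data.frame with columns `i_id`, `j_id`, `weight`.
#' @param ids Full unit id vector (so islands are preserved); defaults to the
#'   ids present in the edge list.
#' @param style,provenance Passed to [spatial_weights()].
#' @return A data.frame, or a `spatial_weights` object respectively.
#' @export
weights_to_edgelist <- function(W) {
  stopifnot(inherits(W, "spatial_weights"))
  tw <- methods::as(W$W, "TsparseMatrix")
  data.frame(i_id = W$ids[tw@i + 1L], j_id = W$ids[tw@j + 1L], weight = tw@x)
}

#' @rdname weights_to_edgelist
#' @export
edgelist_to_weights <- function(edges, ids = NULL, style = "binary",
                                provenance = "edgelist") {
  stopifnot(all(c("i_id", "j_id", "weight") %in% names(edges)))
  if (is.null(ids)) ids <- sort(unique(c(edges$i_id, edges$j_id)))
  i <- match(edges$i_id, ids); j <- match(edges$j_id, ids)
  if (anyNA(i) || anyNA(j)) stop("edge list refers to unknown unit ids", call. = FALSE)
  W <- Matrix::sparseMatrix(i = i, j = j, x = edges$weight,
                            dims = c(length(ids), length(ids)))
  spatial_weights(W, ids = ids, style = style, provenance = provenance)
}
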