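#' Spatial unit table
#'
#' The central data container: one row per spatial unit (zone/district), with a
#' stable identifier, planar centroid coordinates, and arbitrary attribute
#' columns (a count response, covariates, optionally an exposure offset).
#' Geometry is optional: a list of closed polygon rings (two-column matrices)
#' parallel to the rows, used for contiguity weights and GeoJSON output.
#'
#' Coordinates must be in a projected (planar) coordinate system: all distance
#' computations in this package are Euclidean.
#'
#' @param data A data.frame of per-unit attributes.
#' @param id_col Name of the unique-identifier column (created as `unit_id`
#'   from row order when absent).
#' @param coord_cols Character vector of length 2 naming the x and y centroid
#'   coordinate columns.
#' @param geometry Optional list (length `nrow(data)`) of polygon rings, each a
#'   numeric matrix with two columns; the first and last vertex may coincide.
#' @param crs Free-text label for the projected CRS the coordinates are in.
#' @return An object of class `spatial_units` (a data.frame with metadata
#'   attributes).
#' @seealso [unit_coords()], [unit_geometry()], [generate_lattice()]
#' @export
spatial_units <- function(data, id_col = "unit_id", coord_cols = c("x", "y"),
                          geometry = NULL, crs = "projected") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  if (!id_col %in% names(data)) {
    data[[id_col]] <- seq_len(nrow(data))
  }
  missing_coords <- setdiff(coord_cols, names(data))
  if (length(missing_coords)) {
    stop("coordinate column(s) not found: ", paste(missing_coords, collapse = ", "),
         call. = FALSE)
  }
  obj <- structure(data,
                   id_col = id_col,
                   coord_cols = coord_cols,
                   geometry = geometry,
                   crs = crs,
                   class = c("spatial_units", "data.frame"))
  validate_spatial_units(obj)
  obj
}

validate_spatial_units <- function(x) {
  ids <- x[[attr(x, "id_col")]]
  if (anyDuplicated(ids)) stop("unit ids must be unique", call. = FALSE)
  xy <- unit_coords(x)
  if (!all(is.finite(xy))) stop("unit centroids must be finite", call. = FALSE)
  geom <- attr(x, "geometry")
  if (!is.null(geom) && length(geom) != nrow(x)) {
    stop("geometry list must have one element per unit", call. = FALSE)
  }
  invisible(x)
}

#' @export
#' @method print spatial_units
print.spatial_units <- function(x, ...) {
  cat(sprintf("<spatial_units> %d units, CRS: %s, geometry: %s\n",
              nrow(x), attr(x, "crs"),
              if (is.null(attr(x, "geometry"))) "none" else "polygons"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Unit identifiers, coordinates and geometry
#'
#' Accessors for [spatial_units()] objects.
#'
#' @param units A `spatial_units` object.
#' @return `unit_ids`: a vector of identifiers. `unit_coords`: an n x 2 numeric
#'   matrix of planar centroids. `unit_geometry`: the list of polygon rings or
#'   `NULL`. `n_units`: the number of units.
#' @export
unit_ids <- function(units) units[[attr(units, "id_col")]]

#' @rdname unit_ids
#' @export
unit_coords <- function(units) {
  cc <- attr(units, "coord_cols")
  m <- cbind(as.numeric(units[[cc[1]]]), as.numeric(units[[cc[2]]]))
  colnames(m) <- cc
  m
}

#' @rdname unit_ids
#' @export
unit_geometry <- function(units) attr(units, "geometry")

#' @rdname unit_ids
#' @export
n_units <- function(units) nrow(units)

#' Row-subset a spatial unit table
#'
#' Keeps the metadata attributes (id column, coordinates, geometry) in sync,
#' which plain `[` subsetting of the underlying data.frame would not.
#'
#' @param units A `spatial_units` object.
#' @param keep Integer or logical row index.
#' @return A `spatial_units` object with the selected rows.
#' @export
subset_units <- function(units, keep) {
  df <- as.data.frame(units)[keep, , drop = FALSE]
  rownames(df) <- NULL
  geom <- attr(units, "geometry")
  spatial_units(df,
                id_col = attr(units, "id_col"),
                coord_cols = attr(units, "coord_cols"),
                geometry = if (is.null(geom)) NULL else geom[keep],
                crs = attr(units, "crs"))
}

# area-weighted centroid of one polygon ring (shoelace formula)
poly_centroid <- function(ring) {
  ring <- as.matrix(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, ])
  }
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(ring[-n, , drop = FALSE]))
  c(sum((x[-n] + x[-1]) * cross) / (6 * a),
    sum((y[-n] + y[-1]) * cross) / (6 * a))
}
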