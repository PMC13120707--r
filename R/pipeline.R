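# ---- GeoJSON I/O (FeatureCollection of Polygon features) ------------------

read_geojson_units <- function(path, coords = c("x", "y"), id_col = "unit_id",
                               crs = "projected") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("GeoJSON must be a FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  if (!length(feats)) stop("empty FeatureCollection", call. = FALSE)
  geometry <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    gm <- ft$geometry
    if (!is.null(gm)) {
      if (!identical(gm$type, "Polygon")) {
        stop(sprintf("unparseable geometry in feature %d: only Polygon is supported (got %s)",
                     i, gm$type %||% "null"), call. = FALSE)
      }
      ring <- do.call(rbind, lapply(gm$coordinates[[1]],
                                    function(pt) c(pt[[1]], pt[[2]])))
      geometry[[i]] <- ring
    }
    props[[i]] <- ft$properties
  }
  keys <- unique(unlist(lapply(props, names)))
  df <- as.data.frame(lapply(setNames(keys, keys), function(k) {
    vapply(props, function(p) {
      v <- p[[k]]
      if (is.null(v)) NA_real_ else if (is.numeric(v)) v else as.numeric(NA)
    }, numeric(1))
  }))
  # non-numeric property columns (e.g. names) re-read as character
  for (k in keys) {
    if (all(is.na(df[[k]]))) {
      df[[k]] <- vapply(props, function(p) {
        v <- p[[k]]; if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }
  }
  has_geom <- !vapply(geometry, is.null, logical(1))
  if (!all(c(coords) %in% names(df))) {
    if (!all(has_geom)) {
      stop("missing coordinate columns and not all features have geometry",
           call. = FALSE)
    }
    ctd <- t(vapply(geometry, poly_centroid, numeric(2)))
    df[[coords[1]]] <- ctd[, 1]
    df[[coords[2]]] <- ctd[, 2]
  }
  spatial_units(df, id_col = id_col, coord_cols = coords,
                geometry = if (all(has_geom)) geometry else NULL, crs = crs)
}

#' Write spatial units to GeoJSON
#'
#' Serializes a unit table as a GeoJSON FeatureCollection: Polygon features
#' when the table carries geometry, Point features at the centroids
#' otherwise. All attribute columns (or the selected ones) become feature
#' properties.
#'
#' @param units A [spatial_units()] object.
#' @param path Output file path.
#' @param columns Attribute columns to include (default: all).
#' @return The path, invisibly.
#' @export
write_units_geojson <- function(units, path, columns = NULL) {
  df <- as.data.frame(units)
  columns <- columns %||% names(df)
  geom <- unit_geometry(units)
  xy <- unit_coords(units)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    g <- if (!is.null(geom)) {
      ring <- as.matrix(geom[[i]])
      if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ],
                            check.attributes = FALSE))) {
        ring <- rbind(ring, ring[1, ])
      }
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(r) c(ring[r, 1], ring[r, 2]))))
    } else {
      list(type = "Point", coordinates = c(xy[i, 1], xy[i, 2]))
    }
    list(type = "Feature", geometry = g,
         properties = as.list(df[i, columns, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

# ---- table reader ---------------------------------------------------------

looks_geographic <- function(xy) {
  all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)
}

#' Read a spatial unit table from disk
#'
#' Reads CSV (attributes plus x/y centroid columns), GeoJSON (Polygon
#' features; centroids computed from geometry when coordinate columns are
#' absent), or the .dbf attribute table of an ESRI Shapefile (which must then
#' contain x/y columns, as no shapefile geometry reader is used). Rows with
#' missing values in the used columns are dropped with a logged count.
#' Coordinates must already be in a projected planar CRS: input whose
#' coordinate range looks geographic (lon/lat) is rejected, since all
#' distances in this package are Euclidean.
#'
#' @param path Input file.
#' @param format `"csv"`, `"geojson"` or `"shapefile"` (guessed from the
#'   extension by default).
#' @param coords Names of the x and y coordinate columns.
#' @param id_col Unit identifier column (created from row order if absent).
#' @param used_cols Columns that must be complete; rows with missing values
#'   in any of them are dropped (default: all columns).
#' @param crs Label of the projected CRS the coordinates are in.
#' @param assume_projected Skip the geographic-coordinate heuristic for
#'   genuinely small planar extents.
#' @return A [spatial_units()] object.
#' @export
read_spatial_table <- function(path, format = NULL, coords = c("x", "y"),
                               id_col = "unit_id", used_cols = NULL,
                               crs = "projected", assume_projected = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", geojson = "geojson",
                               json = "geojson", shp = "shapefile",
                               dbf = "shapefile",
                               stop("unknown format for ", path, call. = FALSE))
  units <- switch(format,
    csv = {
      df <- read.csv(path)
      miss <- setdiff(coords, names(df))
      if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
      spatial_units(df, id_col = id_col, coord_cols = coords, crs = crs)
    },
    geojson = read_geojson_units(path, coords = coords, id_col = id_col,
                                 crs = crs),
    shapefile = {
      if (!requireNamespace("foreign", quietly = TRUE)) {
        stop("shapefile attribute reading needs the 'foreign' package",
             call. = FALSE)
      }
      dbf <- sub("\\.shp$", ".dbf", path, ignore.case = TRUE)
      if (!file.exists(dbf)) stop("no .dbf attribute table next to ", path,
                                  call. = FALSE)
      df <- foreign::read.dbf(dbf, as.is = TRUE)
      miss <- setdiff(coords, names(df))
      if (length(miss)) {
        stop("shapefile geometry is not parsed; the attribute table must carry ",
             "centroid column(s): ", paste(miss, collapse = ", "), call. = FALSE)
      }
      spatial_units(df, id_col = id_col, coord_cols = coords, crs = crs)
    },
    stop("unknown format: ", format, call. = FALSE))

  used_cols <- used_cols %||% names(as.data.frame(units))
  missing_used <- setdiff(used_cols, names(units))
  if (length(missing_used)) stop("missing column(s): ",
                                 paste(missing_used, collapse = ", "),
                                 call. = FALSE)
  keep <- complete.cases(as.data.frame(units)[used_cols])
  if (any(!keep)) {
    message(sprintf("dropped %d row(s) with missing values in used columns",
                    sum(!keep)))
    units <- subset_units(units, keep)
  }
  xy <- unit_coords(units)
  if (!assume_projected && looks_geographic(xy)) {
    stop("coordinates look geographic (lon/lat); supply data in a projected ",
         "planar CRS (or set assume_projected = TRUE for genuinely small ",
         "planar extents)", call. = FALSE)
  }
  units
}

# ---- configuration --------------------------------------------------------

#' Analysis configuration
#'
#' Bundles every setting of the full zonal analysis: input location and
#' format, variable roles, spatial-weight and kernel choices, screening
#' thresholds, permutation count and the master seed. Round-trips losslessly
#' through JSON via [write_config()] / [read_config()].
#'
#' @param response Response (count) column name.
#' @param covariates Character vector of candidate covariate columns.
#' @param input,format Input path and format for [read_spatial_table()]
#'   (omit when units are passed to [run_full_analysis()] directly).
#' @param offset Optional exposure column name.
#' @param coords,id_col Column roles for the reader.
#' @param assume_projected Skip the reader's geographic-coordinate heuristic
#'   (for genuinely small planar extents).
#' @param weights Moran weight recipe: `"queen"`, `"rook"`, or `"knn:K"`.
#' @param kernel_kind GWNBR kernel, see [kernel_spec()].
#' @param criteria Bandwidth criteria to run (subset of `c("aic", "cv")`).
#' @param bounds Optional bandwidth search bounds.
#' @param vif_threshold,moran_alpha Screening thresholds.
#' @param strict_moran Enforce the Moran screen (default: advisory).
#' @param n_permutations Permutations for Moran/LISA inference.
#' @param seed Master seed, recorded in every output artifact.
#' @param out_dir Output directory.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(response, covariates, input = NULL, format = NULL,
                            offset = NULL, coords = c("x", "y"),
                            id_col = "unit_id", assume_projected = FALSE,
                            weights = "queen",
                            kernel_kind = "adaptive_bisquare",
                            criteria = c("aic", "cv"), bounds = NULL,
                            vif_threshold = 10, moran_alpha = 0.05,
                            strict_moran = FALSE, n_permutations = 199,
                            seed = 1, out_dir = tempfile("gwcrash_run_")) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(covariates), length(covariates) >= 1L,
            all(criteria %in% c("aic", "cv")), length(criteria) >= 1L)
  structure(list(response = response, covariates = covariates, input = input,
                 format = format, offset = offset, coords = coords,
                 id_col = id_col, assume_projected = assume_projected,
                 weights = weights,
                 kernel_kind = kernel_kind, criteria = criteria,
                 bounds = bounds, vif_threshold = vif_threshold,
                 moran_alpha = moran_alpha, strict_moran = strict_moran,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config An `analysis_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  do.call(analysis_config, lst)
}

build_moran_weights <- function(units, recipe) {
  if (identical(recipe, "queen") || identical(recipe, "rook")) {
    if (is.null(unit_geometry(units))) {
      return(row_standardize(knn_weights(units, k = min(8, n_units(units) - 1))))
    }
    return(row_standardize(contiguity_weights(units, recipe)))
  }
  if (grepl("^knn:[0-9]+$", recipe)) {
    k <- as.integer(sub("^knn:", "", recipe))
    return(row_standardize(knn_weights(units, k = k)))
  }
  stop("unknown weights recipe: ", recipe, call. = FALSE)
}

# ---- full pipeline --------------------------------------------------------

#' Run the full zonal crash-frequency analysis
#'
#' End-to-end orchestration in the conventional order: (1) descriptive
#' statistics; (2) global Moran and LISA on the response; (3) per-variable
#' Moran and VIF screening; (4) global OLS, Poisson and NB fits with the
#' Poisson dispersion statistic; (5) GWNBR bandwidth selection under the
#' configured criteria and a fit at each selected bandwidth; (6) a model
#' comparison table with residual Moran diagnostics; (7) local coefficient
#' five-number summaries and per-unit output. All artifacts are written to
#' `config$out_dir` as CSV/GeoJSON plus a JSON run manifest recording the
#' config, seed and package version. A failure in any stage halts with a
#' stage-tagged error; artifacts written by earlier stages are preserved.
#'
#' @param config An [analysis_config()].
#' @param units Optionally, a ready [spatial_units()] table (otherwise read
#'   from `config$input`).
#' @return Invisibly, a list with every stage's objects (`descriptives`,
#'   `moran`, `lisa`, `screening`, `global_fits`, `bandwidths`,
#'   `gwnbr_fits`, `comparison`, `local_summary`, `manifest`).
#' @export
run_full_analysis <- function(config, units = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  out <- function(...) file.path(config$out_dir, ...)

  if (is.null(units)) {
    units <- stage("read", read_spatial_table(
      config$input, format = config$format, coords = config$coords,
      id_col = config$id_col, assume_projected = config$assume_projected,
      used_cols = c(config$response, config$covariates, config$offset)))
  }
  y <- units[[config$response]]
  vars <- config$covariates

  desc <- stage("descriptives", {
    cols <- c(config$response, vars)
    d <- data.frame(variable = cols,
                    min = vapply(cols, function(v) min(units[[v]]), 0),
                    max = vapply(cols, function(v) max(units[[v]]), 0),
                    mean = vapply(cols, function(v) mean(units[[v]]), 0),
                    sd = vapply(cols, function(v) sd(units[[v]]), 0))
    write.csv(d, out("descriptives.csv"), row.names = FALSE)
    d
  })

  W <- stage("weights", build_moran_weights(units, config$weights))

  moran_res <- stage("moran", {
    mt <- global_moran(y, W, n_permutations = config$n_permutations,
                       seed = config$seed)
    write.csv(data.frame(variable = config$response, I = mt$I,
                         expected_I = mt$expected_I, z = mt$z_score,
                         p_analytic = mt$p_analytic,
                         p_permutation = mt$p_permutation %||% NA,
                         seed = config$seed),
              out("moran_response.csv"), row.names = FALSE)
    mt
  })

  lisa_res <- stage("lisa", {
    ls <- local_moran(y, W, n_permutations = config$n_permutations,
                      seed = config$seed)
    write.csv(cbind(as.data.frame(ls), seed = config$seed), out("lisa.csv"),
              row.names = FALSE)
    if (!is.null(unit_geometry(units))) {
      gu <- units
      gu$cluster <- ls$cluster
      gu$local_I <- ls$local_I
      gu$p_local <- ls$p_local
      write_units_geojson(gu, out("lisa.geojson"))
    }
    ls
  })

  screening <- stage("screening", {
    sc <- screen_variables(units, vars, W, alpha = config$moran_alpha,
                           vif_threshold = config$vif_threshold,
                           strict_moran = config$strict_moran,
                           n_permutations = 0)
    tb <- sc$table
    tb$seed <- config$seed
    write.csv(tb, out("screening.csv"), row.names = FALSE)
    sc
  })
  kept <- screening$retained
  fml <- stats::as.formula(paste(config$response, "~",
                                 paste(kept, collapse = " + ")))

  global_fits <- stage("global_models", {
    ols <- fit_ols(units, fml)
    pois <- fit_poisson(units, fml, offset = config$offset)
    nbr <- fit_negbin(units, fml, offset = config$offset)
    coefs <- do.call(rbind, lapply(list(OLSR = ols, PR = pois, NBR = nbr),
                                   function(f) f$coefficients))
    coefs$model <- rep(c("OLSR", "PR", "NBR"),
                       each = nrow(ols$coefficients))
    write.csv(coefs, out("global_models.csv"), row.names = FALSE)
    metrics <- list(seed = config$seed,
                    poisson_dispersion = dispersion_statistic(pois),
                    negbin_dispersion = dispersion_statistic(nbr),
                    negbin_alpha = nbr$alpha,
                    loglik = list(ols = ols$log_likelihood,
                                  poisson = pois$log_likelihood,
                                  negbin = nbr$log_likelihood))
    writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA),
               out("global_metrics.json"))
    list(ols = ols, poisson = pois, negbin = nbr)
  })

  bandwidths <- stage("bandwidth_selection", {
    bw <- lapply(setNames(config$criteria, config$criteria), function(cr) {
      select_bandwidth(units, fml, kernel_kind = config$kernel_kind,
                       criterion = cr, bounds = config$bounds,
                       offset = config$offset)
    })
    evals <- do.call(rbind, lapply(names(bw), function(cr) {
      cbind(criterion = cr, bw[[cr]]$evaluated, seed = config$seed)
    }))
    write.csv(evals, out("bandwidth_search.csv"), row.names = FALSE)
    bw
  })

  gwnbr_fits <- stage("gwnbr", {
    lapply(bandwidths, function(bw) {
      fit_gwnbr(units, fml, kernel_spec(config$kernel_kind, bw$optimum),
                offset = config$offset)
    })
  })

  comparison <- stage("comparison", {
    fits <- c(list(OLSR = global_fits$ols, PR = global_fits$poisson,
                   NBR = global_fits$negbin),
              setNames(gwnbr_fits,
                       paste0("GWNBR", seq_along(gwnbr_fits), "_",
                              toupper(names(gwnbr_fits)))))
    cmp <- compare_models(fits, W)
    write.csv(cbind(as.data.frame(cmp), seed = config$seed),
              out("comparison.csv"), row.names = FALSE)
    cmp
  })

  local_summary <- stage("local_output", {
    main <- gwnbr_fits[[1]]
    sm <- summary(main)
    write.csv(cbind(sm$coefficients, seed = config$seed),
              out("local_summary.csv"), row.names = FALSE)
    long <- do.call(rbind, lapply(colnames(main$local_beta), function(tm) {
      data.frame(unit_id = main$ids, term = tm,
                 estimate = main$local_beta[, tm],
                 se = main$local_se[, tm],
                 t = main$local_tstat[, tm],
                 significant = abs(main$local_tstat[, tm]) > qnorm(0.975))
    }))
    write.csv(long, out("local_estimates.csv"), row.names = FALSE)
    if (!is.null(unit_geometry(units))) {
      gu <- units
      for (tm in colnames(main$local_beta)) {
        safe <- gsub("[^A-Za-z0-9]", "_", tm)
        gu[[paste0("beta_", safe)]] <- main$local_beta[, tm]
        gu[[paste0("sig_", safe)]] <- abs(main$local_tstat[, tm]) > qnorm(0.975)
      }
      gu$alpha_local <- main$local_alpha
      write_units_geojson(gu, out("local.geojson"))
    }
    sm
  })

  manifest <- list(config = unclass(config), seed = config$seed,
                   package = "gwcrash",
                   version = as.character(packageVersion("gwcrash")),
                   r_version = R.version.string,
                   n_units = n_units(units),
                   timings = timings)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), out("manifest.json"))

  invisible(list(units = units, descriptives = desc, weights = W,
                 moran = moran_res, lisa = lisa_res, screening = screening,
                 global_fits = global_fits, bandwidths = bandwidths,
                 gwnbr_fits = gwnbr_fits, comparison = comparison,
                 local_summary = local_summary, manifest = manifest))
}
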