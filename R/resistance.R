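#' Default resistance reclassification table
#'
#' Bands and resistance values for the five movement-resistance factors.
#' Land-use classes map forest/grassland to 20, water to 40, cultivated
#' land to 60, bare land to 80 and construction land to 100 (codes 1-5 by
#' default). Continuous bands are left-open/right-closed, so a boundary
#' value falls in the lower band. The distance factors assign 1 (near-zero
#' resistance) beyond 800 m of a county road / 2000 m of a highway, below
#' the 20 of the nearest band; `monotone = TRUE` in [reclass_factor()]
#' replaces those 1s by 20 for sensitivity analysis.
#'
#' @return named list of band definitions
#' @export
resistance_table_default <- function() {
  list(
    landuse = list(map = c(`1` = 20, `2` = 40, `3` = 60, `4` = 80, `5` = 100),
                   categorical = TRUE),
    vegcover = list(breaks = c(0.15, 0.35, 0.50, 0.65),
                    values = c(100, 80, 60, 40, 20)),
    slope = list(breaks = c(5, 15, 25, 35),
                 values = c(20, 40, 60, 80, 100)),
    dist_county_road = list(breaks = c(150, 300, 450, 600, 800),
                            values = c(20, 40, 60, 80, 100, 1),
                            far_value = 1),
    dist_highway = list(breaks = c(400, 800, 1200, 1600, 2000),
                        values = c(20, 40, 60, 80, 100, 1),
                        far_value = 1)
  )
}

#' Default resistance-factor weights
#'
#' The weighted-overlay weights for (land use, vegetation coverage, slope,
#' distance to county road, distance to highway): 0.095, 0.213, 0.236,
#' 0.118, 0.173. Alternatively, weights can be recomputed as the principal
#' eigenvector of a supplied pairwise comparison matrix (e.g.
#' [resistance_comparison_matrix()]); note the eigenvector of that matrix
#' differs from these defaults, which are used as given.
#'
#' @param matrix optional `esp_pairwise` matrix; when supplied, its
#'   normalized principal eigenvector is returned instead of the defaults.
#' @return named numeric vector of five weights
#' @export
resistance_weights <- function(matrix = NULL) {
  nm <- c("landuse", "vegcover", "slope", "dist_county_road", "dist_highway")
  if (is.null(matrix))
    return(setNames(c(0.095, 0.213, 0.236, 0.118, 0.173), nm))
  setNames(principal_eigen(matrix)$weights, nm)
}

#' Reclassify a raw factor to resistance values
#'
#' Maps every cell of a raw factor raster to its band's resistance value in
#' \{1, 20, 40, 60, 80, 100\} using [resistance_table_default()] (or an
#' override).
#'
#' @param raw raw factor [esp_grid()] (land-use codes, coverage fraction,
#'   slope in degrees, or distance in metres)
#' @param name one of `"landuse"`, `"vegcover"`, `"slope"`,
#'   `"dist_county_road"`, `"dist_highway"`
#' @param table band table, default [resistance_table_default()]
#' @param monotone if `TRUE`, the beyond-range distance value 1 is replaced
#'   by 20 (monotone variant)
#' @return object of class `esp_resist_factor` (fields `name`, `grid`)
#' @export
reclass_factor <- function(raw, name, table = resistance_table_default(),
                           monotone = FALSE) {
  stopifnot(is_esp_grid(raw))
  name <- match.arg(name, names(resistance_table_default()))
  spec <- table[[name]]
  v <- raw$values
  if (isTRUE(spec$categorical)) {
    codes <- unique(v[!is.na(v)])
    unknown <- setdiff(codes, as.numeric(names(spec$map)))
    if (length(unknown))
      stop("unmapped land-use code(s): ", paste(sort(unknown), collapse = ", "))
    out <- matrix(unname(spec$map[as.character(v)]), nrow(v))
  } else {
    vals <- spec$values
    if (monotone && !is.null(spec$far_value))
      vals[vals == spec$far_value] <- 20
    out <- matrix(vals[findInterval(v, spec$breaks, left.open = TRUE) + 1],
                  nrow(v))
  }
  out[is.na(v)] <- NA_real_
  structure(list(name = name, grid = grid_like(raw, out)),
            class = "esp_resist_factor")
}

#' Weighted overlay of resistance factors
#'
#' Cellwise weighted sum of the five reclassified factors: the
#' comprehensive ecological resistance surface. Nodata propagates from any
#' factor.
#'
#' @param factors named list of five `esp_resist_factor` objects (names
#'   `landuse`, `vegcover`, `slope`, `dist_county_road`, `dist_highway`)
#' @param weights named weights, default [resistance_weights()]
#' @return object of class `esp_resistance` (fields `grid`, `weights`)
#' @export
weighted_overlay <- function(factors, weights = resistance_weights()) {
  need <- names(resistance_weights())
  if (!all(need %in% names(factors)))
    stop("missing resistance factor(s): ",
         paste(setdiff(need, names(factors)), collapse = ", "))
  if (!all(need %in% names(weights)) || any(weights[need] <= 0))
    stop("weights must be positive and named for all five factors")
  gs <- lapply(factors[need], function(f) {
    stopifnot(inherits(f, "esp_resist_factor"))
    f$grid
  })
  do.call(check_aligned, gs)
  acc <- 0
  for (nm in need) acc <- acc + weights[[nm]] * gs[[nm]]$values
  structure(list(grid = grid_like(gs[[1]], acc), weights = weights[need]),
            class = "esp_resistance")
}

#' @export
print.esp_resistance <- function(x, ...) {
  cat("esp_resistance surface\n")
  print(x$grid)
  invisible(x)
}
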