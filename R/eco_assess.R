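#' Default factor grading thresholds
#'
#' Grading bands that reclassify the six assessment factors onto the ordinal
#' sensitivity scale \{1, 3, 5, 7, 9\} (1 = low sensitivity, 9 = high).
#' Continuous factors use four ascending interior cuts (left-open /
#' right-closed bands, so a boundary value falls in the lower band):
#' rainfall erosivity `R` (532/560/583/604), topographic relief `LS`
#' (70/123/178/248), aridity index `I` (0.55/0.65/0.75/0.85) and
#' sand-blowing days `W` (100/140/190/250) grade ascending; vegetation
#' coverage `C` (0.55/0.75/0.85/0.95) grades descending (coverage above 0.95
#' is the least sensitive). Soil texture maps the 13 USDA texture codes
#' (1 = heavy clay ... 13 = sand) to grades; silt is least erodible, coarse
#' sand and heavy clay most.
#'
#' @return a named list of band definitions, overridable entry by entry
#' @export
grade_table_default <- function() {
  list(
    R  = list(breaks = c(532, 560, 583, 604), direction = "ascending"),
    LS = list(breaks = c(70, 123, 178, 248), direction = "ascending"),
    C  = list(breaks = c(0.55, 0.75, 0.85, 0.95), direction = "descending"),
    I  = list(breaks = c(0.55, 0.65, 0.75, 0.85), direction = "ascending"),
    W  = list(breaks = c(100, 140, 190, 250), direction = "ascending"),
    soil_texture = list(
      # USDA code -> grade
      map = c(`1` = 7, `2` = 7, `3` = 7, `4` = 3, `5` = 3, `6` = 1,
              `7` = 3, `8` = 5, `9` = 5, `10` = 5, `11` = 3, `12` = 3,
              `13` = 7, `14` = 9),   # 14 reserved for gravel/skeletal soil
      direction = "categorical")
  )
}

#' Grade an assessment factor onto the 1-9 ordinal scale
#'
#' Reclassifies a raw factor raster onto \{1, 3, 5, 7, 9\} using the grading
#' bands in [grade_table_default()] (overridable via `table`). This makes the
#' heterogeneous factors commensurable before they are combined in the
#' sensitivity indices.
#'
#' @param grid raw factor [esp_grid()]
#' @param factor one of `"R"`, `"LS"`, `"C"`, `"soil_texture"`, `"I"`, `"W"`
#' @param table grading table, default [grade_table_default()]
#' @return an object of class `esp_graded` (fields `grid`, `factor`,
#'   `direction`); every non-nodata cell is in \{1, 3, 5, 7, 9\}
#' @export
grade_factor <- function(grid, factor, table = grade_table_default()) {
  stopifnot(is_esp_grid(grid))
  factor <- match.arg(factor, c("R", "LS", "C", "soil_texture", "I", "W"))
  spec <- table[[factor]]
  v <- grid$values
  if (identical(spec$direction, "categorical")) {
    codes <- unique(v[!is.na(v)])
    unknown <- setdiff(codes, as.numeric(names(spec$map)))
    if (length(unknown))
      stop("unknown soil-texture code(s): ", paste(sort(unknown), collapse = ", "))
    g <- matrix(unname(spec$map[as.character(v)]), nrow(v))
    g[is.na(v)] <- NA_real_
  } else {
    band <- findInterval(v, spec$breaks, left.open = TRUE) + 1
    if (identical(spec$direction, "descending")) band <- 6 - band
    g <- matrix(2 * band - 1, nrow(v))
    g[is.na(v)] <- NA_real_
  }
  structure(list(grid = grid_like(grid, g), factor = factor,
                 direction = spec$direction),
            class = "esp_graded")
}

graded_values <- function(x) {
  g <- if (inherits(x, "esp_graded")) x$grid else x
  stopifnot(is_esp_grid(g))
  v <- g$values[!is.na(g$values)]
  if (length(v) && !all(v %in% c(1, 3, 5, 7, 9)))
    stop("graded layer has values outside {1,3,5,7,9}")
  g
}

#' Rainfall erosivity (R factor)
#'
#' `R = sum over months of (-2.6398 + 0.3046 * P_i)` where `P_i` is the
#' long-term mean precipitation of month `i` in mm. The formula is affine in
#' rainfall; months drier than about 8.7 mm contribute negative terms, which
#' are retained (subsequent natural-breaks grading is unaffected by the
#' absolute level).
#'
#' @param monthly_precip list of 12 aligned monthly-mean precipitation grids
#'   (mm)
#' @return an [esp_grid()] of erosivity values
#' @export
rainfall_erosivity <- function(monthly_precip) {
  if (length(monthly_precip) != 12L)
    stop("need exactly 12 monthly precipitation grids")
  do.call(check_aligned, monthly_precip)
  acc <- 0
  for (p in monthly_precip) {
    stopifnot(is_esp_grid(p))
    acc <- acc + (-2.6398 + 0.3046 * p$values)
  }
  grid_like(monthly_precip[[1]], acc)
}

geo_mean4 <- function(a, b, c, d) {
  ga <- graded_values(a); gb <- graded_values(b)
  gc_ <- graded_values(c); gd <- graded_values(d)
  check_aligned(ga, gb, gc_, gd)
  grid_like(ga, (ga$values * gb$values * gc_$values * gd$values)^(1 / 4))
}

#' Sensitivity to soil-and-water loss (SSWL)
#'
#' Fourth root of the product of the graded rainfall-erosivity (R), soil
#' texture (K), topographic relief (LS) and vegetation coverage (C) layers:
#' the geometric mean of the four grades, bounded in `[1, 9]`.
#'
#' @param r_g,k_g,ls_g,c_g graded layers ([grade_factor()] output or grids
#'   already on the 1-9 scale)
#' @return an [esp_grid()] of index values
#' @export
sswl <- function(r_g, k_g, ls_g, c_g) geo_mean4(r_g, k_g, ls_g, c_g)

#' Sensitivity to soil erosion (SSE)
#'
#' Arithmetic mean of the graded relief (LS), rainfall erosivity (R), soil
#' texture (K) and vegetation coverage (C) layers; bounded in `[1, 9]` and,
#' by the AM-GM inequality, never below [sswl()] on the same grades.
#'
#' @param ls_g,r_g,k_g,c_g graded layers
#' @return an [esp_grid()] of index values
#' @export
sse <- function(ls_g, r_g, k_g, c_g) {
  ga <- graded_values(ls_g); gb <- graded_values(r_g)
  gc_ <- graded_values(k_g); gd <- graded_values(c_g)
  check_aligned(ga, gb, gc_, gd)
  grid_like(ga, (ga$values + gb$values + gc_$values + gd$values) / 4)
}

#' Sensitivity to land desertification (SLD)
#'
#' Geometric mean (fourth root of the product) of the graded aridity index
#' (I), sand-blowing days (W), soil texture (K) and vegetation coverage (C).
#'
#' @param i_g,w_g,k_g,c_g graded layers
#' @return an [esp_grid()] of index values
#' @export
sld <- function(i_g, w_g, k_g, c_g) geo_mean4(i_g, w_g, k_g, c_g)

check_weights <- function(weights, n) {
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("need ", n, " positive weights")
  if (abs(sum(weights) - 1) > 1e-6)
    warning(sprintf("weights sum to %.6f, not 1; using them as given",
                    sum(weights)))
  weights
}

#' Composite ecological sensitivity
#'
#' Weighted sum of the three sensitivity indices, by default
#' `0.43 * SSWL + 0.39 * SSE + 0.18 * SLD`. With weights summing to 1 the
#' result is a convex combination bounded by the input extrema.
#'
#' @param sswl,sse,sld index grids
#' @param weights three positive weights (warning if they do not sum to 1)
#' @return an [esp_grid()]
#' @export
composite_sensitivity <- function(sswl, sse, sld,
                                  weights = c(0.43, 0.39, 0.18)) {
  weights <- check_weights(weights, 3L)
  check_aligned(sswl, sse, sld)
  grid_like(sswl, weights[1] * sswl$values + weights[2] * sse$values +
              weights[3] * sld$values)
}

#' Slope in degrees from a DEM
#'
#' Horn's method: slope of the plane fitted to the 3x3 neighbourhood by
#' central differences (edge rows/columns use replicated neighbours).
#'
#' @param dem elevation [esp_grid()] (metres)
#' @return an [esp_grid()] of slope in degrees `[0, 90)`
#' @export
slope_from_dem <- function(dem) {
  stopifnot(is_esp_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad edges
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  idx <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- idx(0, 0); b <- idx(0, 1); cc <- idx(0, 2)
  d <- idx(1, 0);                  f <- idx(1, 2)
  g <- idx(2, 0); h <- idx(2, 1); i <- idx(2, 2)
  cs <- dem$cellsize
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  grid_like(dem, slope)
}

#' Soil-percolation factor from USDA texture codes
#'
#' Divides the USDA texture code (1 = heavy clay ... 13 = sand) by 13,
#' giving an equally spaced percolation index in `(0, 1]` (sandier soils
#' percolate more).
#'
#' @param texture [esp_grid()] of USDA codes 1-13
#' @export
fsic_from_texture <- function(texture) {
  stopifnot(is_esp_grid(texture))
  v <- texture$values
  codes <- v[!is.na(v)]
  if (length(codes) && (any(codes < 1) || any(codes > 13) ||
                        any(codes != round(codes))))
    stop("texture codes must be integers in 1..13")
  grid_like(texture, v / 13)
}

check_unit_interval <- function(...) {
  gs <- list(...)
  for (g in gs) {
    stopifnot(is_esp_grid(g))
    v <- g$values[!is.na(g$values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("service-formula inputs must be normalized to [0, 1]")
  }
  invisible(TRUE)
}

#' Water-retention service index (WR)
#'
#' `WR = NPP_mean * F_sic * F_pre * (1 - F_sio)`: productivity times soil
#' percolation times precipitation, discounted by slope. All inputs must be
#' normalized to `[0, 1]` (`F_sic` as texture code / 13), so `WR` is in
#' `[0, 1]`.
#'
#' @param npp,fsic,fpre,fsio aligned normalized grids
#' @return an [esp_grid()]
#' @export
water_retention <- function(npp, fsic, fpre, fsio) {
  check_unit_interval(npp, fsic, fpre, fsio)
  check_aligned(npp, fsic, fpre, fsio)
  grid_like(npp, npp$values * fsic$values * fpre$values * (1 - fsio$values))
}

#' Soil-and-water conservation service index (Spro)
#'
#' `Spro = NPP_mean * (1 - K) * (1 - F_sio)` with `K` the normalized soil
#' erodibility and `F_sio` the slope factor; all inputs in `[0, 1]`.
#'
#' @param npp,k_norm,fsio aligned normalized grids
#' @return an [esp_grid()]
#' @export
soil_conservation <- function(npp, k_norm, fsio) {
  check_unit_interval(npp, k_norm, fsio)
  check_aligned(npp, k_norm, fsio)
  grid_like(npp, npp$values * (1 - k_norm$values) * (1 - fsio$values))
}

#' Biodiversity-maintenance service index (Sbio)
#'
#' `Sbio = NPP_mean * F_pre * F_tem * (1 - F_alt)` with `F_alt` the
#' normalized elevation (higher cells contribute less); all inputs in
#' `[0, 1]`.
#'
#' @param npp,fpre,ftem,falt aligned normalized grids
#' @return an [esp_grid()]
#' @export
biodiversity_service <- function(npp, fpre, ftem, falt) {
  check_unit_interval(npp, fpre, ftem, falt)
  check_aligned(npp, fpre, ftem, falt)
  grid_like(npp, npp$values * fpre$values * ftem$values * (1 - falt$values))
}

#' Composite ecosystem-service importance
#'
#' Weighted sum of the three service indices, by default
#' `0.45 * WR + 0.30 * Spro + 0.25 * Sbio`.
#'
#' @param wr,spro,sbio index grids
#' @param weights three positive weights (warning if they do not sum to 1)
#' @return an [esp_grid()]
#' @export
composite_importance <- function(wr, spro, sbio,
                                 weights = c(0.45, 0.30, 0.25)) {
  weights <- check_weights(weights, 3L)
  check_aligned(wr, spro, sbio)
  grid_like(wr, weights[1] * wr$values + weights[2] * spro$values +
              weights[3] * sbio$values)
}

#' Superpose sensitivity and importance into the environment assessment
#'
#' Min-max normalizes the composite sensitivity and importance layers,
#' combines them by spatial superposition (default equal weights), and
#' classifies each of the three scores into `k` classes by Jenks natural
#' breaks (class 1 = low sensitivity / generally important, class `k` =
#' high sensitivity / extremely important).
#'
#' @param sensitivity,importance composite score grids
#' @param weights two positive superposition weights (default 0.5/0.5)
#' @param k number of classes (default 5)
#' @return an object of class `esp_assessment`: grids
#'   `sensitivity_class`, `importance_class`, `environment_class` plus the
#'   continuous `environment_score`
#' @export
superpose_environment <- function(sensitivity, importance,
                                  weights = c(0.5, 0.5), k = 5) {
  weights <- check_weights(weights, 2L)
  check_aligned(sensitivity, importance)
  sn <- minmax_normalize(sensitivity)
  im <- minmax_normalize(importance)
  env <- grid_like(sn, weights[1] * sn$values + weights[2] * im$values)
  cls <- function(g) classify(g, jenks_breaks(g, k))
  structure(list(sensitivity_class = cls(sn),
                 importance_class = cls(im),
                 environment_class = cls(env),
                 environment_score = env, k = k),
            class = "esp_assessment")
}
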