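# Run `code` with a temporarily seeded RNG, restoring any prior state, so
# generation is reproducible without touching the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur by banded-matrix multiplication; truncated at
# 3 sigma. Deterministic and platform-stable (no FFT).
gauss_blur <- function(m, sigma) {
  band <- function(n) {
    r <- ceiling(3 * sigma)
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    B <- matrix(0, n, n)
    for (o in (-r):r) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1 & j <= n
      B[cbind(idx[ok], j[ok])] <- k[o + r + 1]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# standardized smooth random field (mean 0, sd 1)
smooth_field <- function(nr, nc, sigma) {
  f <- gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic landscape bundle
#'
#' Produces a complete, aligned set of input layers with the statistical
#' structure the pipeline expects from real mountainous-basin data:
#' spatially autocorrelated continuous fields (autocorrelation range about
#' 10 cells), a DEM trending high in the northwest and low in the
#' southeast, monthly precipitation averaging about 1700 mm per year with
#' an elevation-correlated anomaly, NPP and vegetation coverage positively
#' correlated with each other and suppressed near roads, patchy categorical
#' land-use (forest/grassland majority of about 80 percent, construction
#' clustered along roads) and soil-texture maps, and a few road polylines.
#' Five high-ecological-value patches are planted (elevated NPP, rainfall,
#' temperature, aridity, wind and local relief, reduced vegetation
#' coverage), so that the downstream assessment recovers them as
#' extremely-important ecological sources; their centres are recorded in
#' `truth`.
#'
#' @param seed integer seed; the same seed reproduces the bundle exactly
#' @param n_rows,n_cols grid dimensions (at least 32 x 32)
#' @param cellsize cell size in metres (default 1000)
#' @return a list of class `esp_landscape` with grids `dem`,
#'   `monthly_precip` (list of 12), `npp`, `temperature`, `aridity`,
#'   `wind_days`, `soil_texture`, `landuse`, `vegcover`; `roads` (named
#'   list of segment data.frames `county`, `highway`); and `truth` (seed,
#'   planted patch centres and radius)
#' @export
make_landscape <- function(seed, n_rows = 200, n_cols = 200, cellsize = 1000) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 32L || n_cols < 32L)
    stop("landscape must be at least 32 x 32 cells")
  with_seed(seed, {
    nr <- n_rows; nc <- n_cols
    template <- esp_grid(matrix(0, nr, nc), cellsize,
                         origin = c(0, nr * cellsize))
    as_grid <- function(m) grid_like(template, m)

    # planted high-value patch centres: fixed layout fractions, small jitter
    frac <- cbind(r = c(0.20, 0.25, 0.50, 0.75, 0.80),
                  c = c(0.20, 0.70, 0.45, 0.20, 0.75))
    centres <- cbind(
      pmin(pmax(round(frac[, 1] * nr) +
                  sample(-2:2, nrow(frac), replace = TRUE), 8L), nr - 8L),
      pmin(pmax(round(frac[, 2] * nc) +
                  sample(-2:2, nrow(frac), replace = TRUE), 8L), nc - 8L))
    radius <- 4.5   # cells; quartic plateau bump
    rowm <- matrix(seq_len(nr), nr, nc)
    colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    bump <- matrix(0, nr, nc)
    for (i in seq_len(nrow(centres))) {
      d2 <- (rowm - centres[i, 1])^2 + (colm - centres[i, 2])^2
      bump <- pmax(bump, exp(-(sqrt(d2) / radius)^4))
    }

    # shared fields induce the NPP/vegcover correlation
    f_shared <- smooth_field(nr, nc, 5)
    f_dem <- smooth_field(nr, nc, 8)
    f_pre <- smooth_field(nr, nc, 8)
    f_own <- smooth_field(nr, nc, 5)
    f_cult <- smooth_field(nr, nc, 6)
    f_water <- smooth_field(nr, nc, 4)
    f_bare <- smooth_field(nr, nc, 3)
    f_tex1 <- smooth_field(nr, nc, 7); f_tex2 <- smooth_field(nr, nc, 7)
    f_tex3 <- smooth_field(nr, nc, 7)

    # DEM: NW-high / SE-low trend + smooth field + planted local ruggedness
    trend <- ((nr - rowm) / nr + (nc - colm) / nc) / 2
    ridge <- sin(2 * pi * rowm / 6) * sin(2 * pi * colm / 6)
    dem_smooth <- 200 + 1200 * trend + 250 * f_dem
    dem <- dem_smooth + 150 * bump * ridge

    # roads (map units); avoid the planted patch centres
    W <- nc * cellsize; H <- nr * cellsize
    yat <- function(fr) H - fr * H   # row fraction -> y
    highway <- data.frame(
      x1 = c(0, 0.45 * W), y1 = c(yat(0.60), yat(0.64)),
      x2 = c(0.45 * W, W), y2 = c(yat(0.64), yat(0.58)))
    county <- data.frame(
      x1 = c(0.32 * W, 0.32 * W, 0, 0.60 * W),
      y1 = c(H, yat(0.55), yat(0.92), yat(0.88)),
      x2 = c(0.32 * W, 0.35 * W, 0.60 * W, W),
      y2 = c(yat(0.55), yat(1.0) + 1, yat(0.88), yat(0.95)))
    roads <- list(county = county, highway = highway)
    road_mask <- rasterize_segments(template, rbind(county, highway))
    droad <- cpp_edt(road_mask, cellsize)

    # vegetation coverage and NPP: correlated, road-suppressed, patch signal
    f_v <- 0.7 * f_shared + 0.3 * f_own
    vegcover <- clamp(0.88 + 0.06 * f_v - 0.18 * exp(-droad / 2000) -
                        0.28 * bump, 0.05, 0.995)
    npp <- clamp(450 + 160 * f_v - 120 * exp(-droad / 2500) + 520 * bump,
                 40, Inf)

    # monthly precipitation: seasonal monsoon profile scaled to ~1700 mm/yr
    season <- c(0.5, 0.6, 0.9, 1.2, 1.6, 1.9, 1.5, 1.3, 0.9, 0.7, 0.4, 0.5)
    season <- season * 12 / sum(season)
    dem_anom <- (dem_smooth - mean(dem_smooth)) / stats::sd(dem_smooth)
    wet <- 1 + 0.10 * dem_anom + 0.05 * f_pre + 0.28 * bump
    monthly_precip <- lapply(season, function(s)
      as_grid(clamp((1700 / 12) * s * wet, 0, Inf)))

    # temperature: lapse with smooth elevation, slightly warmer at patches
    temperature <- 21 - 0.005 * (dem_smooth - min(dem_smooth)) +
      0.6 * f_own + 2.5 * bump

    # aridity index and sand-blowing days: background low, planted high
    aridity <- clamp(0.45 + 0.10 * f_pre * (-1) + 0.08 * f_own + 0.5 * bump,
                     0.05, 1.5)
    wind_days <- clamp(120 + 45 * f_shared + 190 * bump, 0, Inf)

    # soil texture: patchy argmax of smooth fields over four USDA codes;
    # planted patches get sandy clay loam (code 10)
    tex_codes <- c(6, 7, 9, 11)   # silt, silt loam, loam, sandy loam
    stack <- array(c(f_tex1, f_tex2, f_tex3, 0.5 * f_tex1 - f_tex2),
                   dim = c(nr, nc, 4))
    tex_idx <- apply(stack, c(1, 2), which.max)
    soil_texture <- matrix(tex_codes[tex_idx], nr)
    soil_texture[bump > 0.5] <- 10

    # land use: forest/grass background, smoothed-field cultivation blobs,
    # water, bare spots, construction along roads; patches forced to forest
    landuse <- matrix(1, nr, nc)
    landuse[f_cult > stats::quantile(f_cult, 0.85)] <- 3
    landuse[f_water > stats::quantile(f_water, 0.985)] <- 2
    landuse[f_bare > stats::quantile(f_bare, 0.998)] <- 4
    constr <- droad < 1.8 * cellsize & matrix(stats::runif(nr * nc), nr) < 0.75
    landuse[constr] <- 5
    landuse[bump > 0.4] <- 1

    structure(list(
      dem = as_grid(dem),
      monthly_precip = monthly_precip,
      npp = as_grid(npp),
      temperature = as_grid(temperature),
      aridity = as_grid(aridity),
      wind_days = as_grid(wind_days),
      soil_texture = as_grid(soil_texture),
      landuse = as_grid(landuse),
      vegcover = as_grid(vegcover),
      roads = roads,
      truth = list(seed = seed, centres = centres, radius_cells = radius,
                   n_rows = nr, n_cols = nc, cellsize = cellsize)),
      class = "esp_landscape")
  })
}

#' @export
print.esp_landscape <- function(x, ...) {
  cat(sprintf("esp_landscape: %d x %d cells at %g m (seed %d)\n",
              x$truth$n_rows, x$truth$n_cols, x$truth$cellsize, x$truth$seed))
  cat(sprintf("  %d planted patch centres, %d road segments\n",
              nrow(x$truth$centres),
              nrow(x$roads$county) + nrow(x$roads$highway)))
  invisible(x)
}

#' Hand-constructed fixtures with exactly known answers
#'
#' Tiny deterministic inputs for exercising individual pipeline stages:
#'
#' * `"two_patches_300m"`: 8 x 12 class grid (cellsize 100 m) with two
#'   class-5 patches whose nearest cell centres are 300 m apart.
#' * `"two_patches_600m"`: same layout with a 600 m separation.
#' * `"uniform_surface"`: constant resistance 2 (cellsize 100 m) with two
#'   single-cell sources 7 orthogonal steps apart on one row, so the
#'   least-cost corridor costs 2 * 100 * 7 = 1400.
#' * `"bottleneck_neck"`: two open rooms joined by a single-cell neck;
#'   current flow between the flanking source columns concentrates at the
#'   neck cell.
#' * `"jenks_six_values"`: the vector (1, 2, 3, 10, 11, 12), whose optimal
#'   2-class partition splits between 3 and 10.
#' * `"table1_band_probe"`: 1 x 5 grids of raw factor values probing the
#'   grading bands for R, LS and C.
#'
#' @param name fixture name (see above)
#' @return a grid, list or vector depending on the fixture
#' @export
make_fixture <- function(name) {
  catalogue <- c("two_patches_300m", "two_patches_600m", "uniform_surface",
                 "bottleneck_neck", "jenks_six_values", "table1_band_probe")
  if (!name %in% catalogue)
    stop("unknown fixture '", name, "'; catalogue: ",
         paste(catalogue, collapse = ", "))
  two_patches <- function(gap_cols) {
    m <- matrix(1, 8, 12)
    m[3:5, 2:3] <- 5
    m[3:5, (3 + gap_cols):(4 + gap_cols)] <- 5
    esp_grid(m, cellsize = 100)
  }
  switch(name,
    two_patches_300m = two_patches(3),
    two_patches_600m = two_patches(6),
    uniform_surface = list(
      surface = esp_grid(matrix(2, 11, 11), cellsize = 100),
      a = matrix(c(6L, 2L), 1), b = matrix(c(6L, 9L), 1),
      expected_cost = 2 * 100 * 7),
    bottleneck_neck = {
      m <- matrix(1, 11, 11)
      m[, 6] <- NA_real_
      m[6, 6] <- 1
      list(surface = esp_grid(m, cellsize = 100),
           a = cbind(1:11, 1L), b = cbind(1:11, 11L),
           neck = c(6L, 6L))
    },
    jenks_six_values = c(1, 2, 3, 10, 11, 12),
    table1_band_probe = list(
      R = esp_grid(matrix(c(500, 550, 570, 590, 650), 1), cellsize = 1000),
      LS = esp_grid(matrix(c(50, 100, 150, 200, 300), 1), cellsize = 1000),
      C = esp_grid(matrix(c(0.96, 0.90, 0.80, 0.60, 0.40), 1),
                   cellsize = 1000))
  )
}

#' Write a landscape bundle to a directory
#'
#' Writes every raster layer as an ASCII grid, the road segments as plain
#' text (`x1 y1 x2 y2` per line), and a YAML manifest recording the seed,
#' dimensions and planted truth.
#'
#' @param bundle an `esp_landscape` from [make_landscape()]
#' @param dir destination directory (created if needed)
#' @export
write_landscape <- function(bundle, dir) {
  stopifnot(inherits(bundle, "esp_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("dem", "npp", "temperature", "aridity", "wind_days",
               "soil_texture", "landuse", "vegcover"))
    write_grid(bundle[[nm]], file.path(dir, paste0(nm, ".asc")))
  for (m in 1:12)
    write_grid(bundle$monthly_precip[[m]],
               file.path(dir, sprintf("precip_%02d.asc", m)))
  for (nm in names(bundle$roads)) {
    seg <- bundle$roads[[nm]]
    writeLines(sprintf("%.6g %.6g %.6g %.6g", seg$x1, seg$y1, seg$x2, seg$y2),
               file.path(dir, paste0("roads_", nm, ".txt")))
  }
  tr <- bundle$truth
  yaml::write_yaml(list(seed = tr$seed, n_rows = tr$n_rows,
                        n_cols = tr$n_cols, cellsize = tr$cellsize,
                        radius_cells = tr$radius_cells,
                        centres = apply(tr$centres, 1, function(x)
                          list(row = x[1], col = x[2]), simplify = FALSE)),
                   file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read road segments from a plain-text file
#'
#' One segment per line: `x1 y1 x2 y2` in map units; blank lines and
#' `#` comments ignored.
#'
#' @param path file path
#' @return data.frame with columns `x1`, `y1`, `x2`, `y2`
#' @export
read_segments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- lapply(strsplit(lines, "\\s+"), as.numeric)
  if (any(lengths(vals) != 4L)) stop("each segment line needs x1 y1 x2 y2")
  m <- do.call(rbind, vals)
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
}
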