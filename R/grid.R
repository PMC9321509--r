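#' @useDynLib espmcr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

#' Create a raster grid
#'
#' The grid is the universal currency of the pipeline: a 2D array of values
#' with square cells of known size, a georeferenced top-left origin and a
#' nodata sentinel. Row 1 is the northernmost row; cell values refer to cell
#' centres; areas are `cell count * cellsize^2`. Nodata cells are held as
#' `NA` internally and every arithmetic operation propagates them.
#'
#' @param values numeric matrix (rows = north to south). `NA` marks nodata.
#' @param cellsize cell edge length in metres (square cells).
#' @param origin numeric length-2, `(x, y)` of the top-left corner in map
#'   units (metres).
#' @param nodata sentinel written to / read from files for nodata cells.
#' @return an object of class `esp_grid`.
#' @examples
#' g <- esp_grid(matrix(1:9, 3, 3, byrow = TRUE), cellsize = 100)
#' g
#' @export
esp_grid <- function(values, cellsize, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid must have at least one row and one column")
  if (length(origin) != 2L) stop("origin must be (x, y)")
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "esp_grid")
}

#' @export
print.esp_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("esp_grid: %d x %d cells, cellsize %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  values: min %.4g, max %.4g, nodata cells: %d\n",
                min(v), max(v), sum(is.na(x$values))))
  else cat("  all cells nodata\n")
  invisible(x)
}

#' Test for grid objects
#' @param x object to test
#' @export
is_esp_grid <- function(x) inherits(x, "esp_grid")

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff they have identical shape, cellsize and origin.
#' All multi-grid operations require alignment.
#'
#' @param a,b `esp_grid` objects
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_aligned <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grids_aligned(gs[[1]], gs[[i]]))
      stop("grids are not aligned (shape, cellsize and origin must match)")
  invisible(TRUE)
}

# keep metadata of `g`, replace values
grid_like <- function(g, values) {
  out <- g
  out$values <- values
  out
}

#' @export
Ops.esp_grid <- function(e1, e2) {
  if (missing(e2)) {
    return(grid_like(e1, get(.Generic)(e1$values)))
  }
  if (is_esp_grid(e1) && is_esp_grid(e2)) {
    check_aligned(e1, e2)
    v <- get(.Generic)(e1$values, e2$values)
    return(grid_like(e1, v))
  }
  if (is_esp_grid(e1)) return(grid_like(e1, get(.Generic)(e1$values, e2)))
  grid_like(e2, get(.Generic)(e1, e2$values))
}

#' Read a raster grid from disk
#'
#' Supports the Esri ASCII grid format (`NCOLS/NROWS/XLLCORNER/YLLCORNER/`
#' `CELLSIZE/NODATA_value` header followed by rows of values, northernmost
#' row first). Cells equal to the nodata sentinel are flagged nodata.
#'
#' @param path file path
#' @param format raster format; `"ascii_grid"` is supported.
#' @return an [esp_grid()]
#' @export
read_grid <- function(path, format = "ascii_grid") {
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "geotiff")
    stop("geotiff I/O is not supported; use format = \"ascii_grid\"")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed ASCII grid header: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("ASCII grid header missing keys: ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  if (anyNA(body)) stop("non-numeric cell values in ASCII grid body")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, header says %d x %d = %d",
                 length(body), nr, nc, nr * nc))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  esp_grid(m, cellsize = hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
           nodata = nodata)
}

#' Write a raster grid to disk
#'
#' Writes the Esri ASCII grid format; [read_grid()] of the result returns an
#' equal grid. Grids whose non-nodata values are all whole numbers (class
#' codes) are written as integers.
#'
#' @param grid an [esp_grid()]
#' @param path destination file path
#' @param format raster format; `"ascii_grid"` is supported.
#' @export
write_grid <- function(grid, path, format = "ascii_grid") {
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "geotiff")
    stop("geotiff I/O is not supported; use format = \"ascii_grid\"")
  stopifnot(is_esp_grid(grid))
  m <- grid$values
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(sprintf("NCOLS %d", nc),
           sprintf("NROWS %d", nr),
           sprintf("XLLCORNER %.10g", grid$origin[1]),
           sprintf("YLLCORNER %.10g", grid$origin[2] - nr * grid$cellsize),
           sprintf("CELLSIZE %.10g", grid$cellsize),
           sprintf("NODATA_value %.10g", grid$nodata))
  vals <- m
  vals[is.na(vals)] <- grid$nodata
  finite <- m[!is.na(m)]
  as_int <- length(finite) == 0L || all(finite == round(finite))
  fmt <- function(row) paste(
    if (as_int) format(row, scientific = FALSE, trim = TRUE)
    else format(row, digits = 15, scientific = FALSE, trim = TRUE),
    collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (r in seq_len(nr)) writeLines(fmt(vals[r, ]), con)
  invisible(path)
}

#' Focal range (local relief)
#'
#' For each cell, the difference between the maximum and minimum value in
#' the square window centred on it. Windows are truncated at the grid edge;
#' nodata cells are excluded from the extremes. Used to derive topographic
#' relief (LS) from a DEM.
#'
#' @param grid an [esp_grid()]
#' @param window odd window side length in cells (`window >= 1`)
#' @return an [esp_grid()] of ranges
#' @export
focal_range <- function(grid, window) {
  stopifnot(is_esp_grid(grid))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  grid_like(grid, cpp_focal_range(grid$values, window))
}

# Rasterize line segments onto a grid template: returns a logical matrix
# marking every cell whose footprint is crossed by a segment (sampled at
# quarter-cell steps, which cannot skip a cell).
rasterize_segments <- function(grid, segments) {
  m <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  cs <- grid$cellsize
  ox <- grid$origin[1]; oy <- grid$origin[2]
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(nrow(segments))) {
    x1 <- segments$x1[s]; y1 <- segments$y1[s]
    x2 <- segments$x2[s]; y2 <- segments$y2[s]
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    n <- max(2L, ceiling(len / (cs / 4)) + 1L)
    t <- seq(0, 1, length.out = n)
    px <- x1 + t * (x2 - x1); py <- y1 + t * (y2 - y1)
    col <- floor((px - ox) / cs) + 1L
    row <- floor((oy - py) / cs) + 1L
    keep <- row >= 1L & row <= nr & col >= 1L & col <= nc
    m[cbind(row[keep], col[keep])] <- TRUE
  }
  m
}

#' Euclidean distance to features
#'
#' Distance in metres from every cell centre to the nearest feature. Line
#' features are rasterized onto the grid template first; distance is then an
#' exact Euclidean distance transform between cell centres. Used for the
#' distance-to-road resistance factors.
#'
#' @param grid an [esp_grid()] providing the template (values are ignored)
#' @param features either a data.frame of line segments with columns
#'   `x1, y1, x2, y2` in map units, or a two-column matrix of `(row, col)`
#'   marked cells, or a logical matrix of marked cells.
#' @return an [esp_grid()] of distances (0 on feature cells)
#' @export
euclidean_distance <- function(grid, features) {
  stopifnot(is_esp_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (is.data.frame(features)) {
    if (!all(c("x1", "y1", "x2", "y2") %in% names(features)))
      stop("segment features need columns x1, y1, x2, y2")
    if (nrow(features) == 0L) stop("empty feature list")
    mask <- rasterize_segments(grid, features)
  } else if (is.logical(features) && is.matrix(features)) {
    mask <- features
  } else if (is.matrix(features) && ncol(features) == 2L) {
    if (nrow(features) == 0L) stop("empty feature list")
    mask <- matrix(FALSE, nr, nc)
    mask[features] <- TRUE
  } else stop("features must be segments, (row, col) cells or a logical mask")
  if (!any(mask, na.rm = TRUE)) stop("no feature falls inside the grid")
  mask[is.na(mask)] <- FALSE
  grid_like(grid, cpp_edt(mask, grid$cellsize))
}

#' Min-max normalization
#'
#' Affine rescaling of all non-nodata cells to `[0, 1]` (minimum to 0,
#' maximum to 1). Monotone, so cell ordering is preserved. Nodata cells are
#' untouched.
#'
#' @param grid an [esp_grid()] with at least two distinct non-nodata values
#' @export
minmax_normalize <- function(grid) {
  stopifnot(is_esp_grid(grid))
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("cannot normalize a constant (or all-nodata) grid")
  grid_like(grid, (v - rng[1]) / (rng[2] - rng[1]))
}

#' Jenks natural-breaks classification boundaries
#'
#' Fisher's optimal contiguous partition of the values into `k` classes
#' minimising total within-class sum of squared deviations. Deterministic:
#' when more than 10,000 finite values are supplied (e.g. a large raster),
#' breaks are computed on a uniform subsample of 10,000 values taken in
#' stride order (no randomness). For a grid, values are taken in row-major
#' (north-to-south, west-to-east) order.
#'
#' @param values numeric vector or [esp_grid()]
#' @param k number of classes (`>= 1`, at most the number of distinct values)
#' @return an object of class `esp_breaks`: list with `k`, `breaks` (the
#'   `k - 1` ascending interior cut values, each the maximum of its class)
#'   and `labels` (`1:k`, 1 = lowest-value class).
#' @export
jenks_breaks <- function(values, k) {
  if (is_esp_grid(values)) values <- as.vector(t(values$values))
  values <- values[!is.na(values)]
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (length(unique(values)) < k)
    stop("need at least k distinct values for k classes")
  if (length(values) > 10000L) {
    idx <- unique(as.integer(round(seq(1, length(values), length.out = 10000L))))
    values <- values[idx]
  }
  x <- sort(values)
  if (k == 1L) {
    return(structure(list(k = 1L, breaks = numeric(0), labels = 1L),
                     class = "esp_breaks"))
  }
  last <- cpp_fisher_jenks(x, k)
  structure(list(k = k, breaks = x[last[-k]], labels = seq_len(k)),
            class = "esp_breaks")
}

#' @export
print.esp_breaks <- function(x, ...) {
  cat(sprintf("esp_breaks: %d classes, cuts: %s\n", x$k,
              paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

#' Classify a grid with break values
#'
#' Values at or below the first break map to class 1, values above the last
#' break to class `k`; interval membership is left-open/right-closed, so the
#' classification is monotone non-decreasing in the cell value.
#'
#' @param grid an [esp_grid()] (or numeric vector)
#' @param breaks an `esp_breaks` object from [jenks_breaks()], or a numeric
#'   vector of ascending interior cut values.
#' @return an [esp_grid()] (or vector) of integer classes `1..k`
#' @export
classify <- function(grid, breaks) {
  cuts <- if (inherits(breaks, "esp_breaks")) breaks$breaks else sort(breaks)
  f <- function(v) findInterval(v, cuts, left.open = TRUE) + 1
  if (is_esp_grid(grid)) {
    v <- f(grid$values)
    v[is.na(grid$values)] <- NA_real_
    return(grid_like(grid, matrix(v, nrow(grid$values))))
  }
  out <- f(grid)
  out[is.na(grid)] <- NA
  out
}

#' Inverse-distance-weighted interpolation
#'
#' Simple IDW (power `p`) of scattered point values onto a grid template.
#' Provided as a convenience for gridding station-style data; the synthetic
#' generator produces grids directly and does not use it.
#'
#' @param grid template [esp_grid()]
#' @param points data.frame with columns `x`, `y`, `value`
#' @param power IDW power (default 2)
#' @export
idw_interpolate <- function(grid, points, power = 2) {
  stopifnot(is_esp_grid(grid), all(c("x", "y", "value") %in% names(points)))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cellsize
  cx <- grid$origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- grid$origin[2] - (seq_len(nr) - 0.5) * cs
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    dx <- outer(points$x, cx, function(p, q) (p - q)^2)
    d2 <- dx + (points$y - cy[r])^2
    w <- 1 / pmax(d2, 1e-12)^(power / 2)
    out[r, ] <- colSums(w * points$value) / colSums(w)
    exact <- apply(d2, 2, function(col) {
      i <- which(col < 1e-12)
      if (length(i)) points$value[i[1]] else NA_real_
    })
    hit <- !is.na(exact)
    out[r, hit] <- exact[hit]
  }
  grid_like(grid, out)
}
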