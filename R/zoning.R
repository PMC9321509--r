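#' Ecological-safety zoning of a cumulative-resistance surface
#'
#' Classifies the source-based cumulative-resistance (cost) surface into
#' `k` safety classes by Jenks natural breaks. The higher the accumulated
#' resistance, the lower the safety: class 1 (lowest cost) is the high
#' ecological safety zone, class `k` the low safety zone. Set
#' `use_raw_surface = TRUE` to classify a raw weighted resistance surface
#' instead of a cost surface.
#'
#' @param cost an `esp_costdist` (from [cost_distance()]), or an
#'   [esp_grid()] / `esp_resistance` when `use_raw_surface = TRUE`
#' @param k number of zones (default 5)
#' @param use_raw_surface classify the supplied grid directly
#' @return object of class `esp_zones`: `zone_grid` (1 = high safety ...
#'   `k` = low safety), `areas` table (`zone`, `area_km2`, `percent`,
#'   percentages summing to 100) and the `breaks` used
#' @export
safety_zones <- function(cost, k = 5, use_raw_surface = FALSE) {
  g <- if (inherits(cost, "esp_costdist")) {
    cost$cost
  } else if (use_raw_surface) {
    resist_grid_of(cost)
  } else if (is_esp_grid(cost)) {
    cost
  } else stop("cost must be an esp_costdist or a grid")
  v <- g$values[!is.na(g$values)]
  if (!length(v)) stop("cost surface has no finite cells")
  if (length(unique(v)) < k)
    stop(sprintf("only %d distinct cost values; choose k <= that",
                 length(unique(v))))
  br <- jenks_breaks(g, k)
  zg <- classify(g, br)
  tab <- table(zg$values)
  areas <- data.frame(zone = as.integer(names(tab)),
                      area_km2 = as.numeric(tab) * g$cellsize^2 / 1e6)
  # report every zone id, even empty ones
  areas <- merge(data.frame(zone = seq_len(k)), areas, all.x = TRUE)
  areas$area_km2[is.na(areas$area_km2)] <- 0
  areas$percent <- 100 * areas$area_km2 / sum(areas$area_km2)
  structure(list(zone_grid = zg, areas = areas, breaks = br, k = k),
            class = "esp_zones")
}

#' @export
print.esp_zones <- function(x, ...) {
  cat(sprintf("esp_zones: %d classes (1 = high safety)\n", x$k))
  print(x$areas, row.names = FALSE)
  invisible(x)
}

#' Map safety zones to policy areas
#'
#' Coarsens the safety zones into the three policy areas: by default the
#' low and lower safety zones (classes `k` and `k - 1`) form the ecological
#' restoration area, the medium and higher safety zones the ecological
#' control area, and the high safety zone (class 1) the ecological
#' conservation area. The mapping must cover every zone class.
#'
#' @param zones an `esp_zones` object
#' @param mapping character vector of length `zones$k` giving the policy
#'   ("conservation", "control" or "restoration") of each zone class in
#'   order 1..k
#' @return object of class `esp_policy`: `policy_grid` (1 = conservation,
#'   2 = control, 3 = restoration), `areas` per policy (percent sums to
#'   100), and the mapping used
#' @export
policy_partition <- function(zones,
                             mapping = c("conservation", "control", "control",
                                         "restoration", "restoration")) {
  stopifnot(inherits(zones, "esp_zones"))
  if (length(mapping) != zones$k)
    stop("mapping must give a policy for each of the ", zones$k, " classes")
  levels <- c("conservation", "control", "restoration")
  if (!all(mapping %in% levels))
    stop("policies must be one of: ", paste(levels, collapse = ", "))
  z <- zones$zone_grid$values
  code <- match(mapping, levels)
  pv <- matrix(code[z], nrow(z))
  pv[is.na(z)] <- NA_real_
  pg <- grid_like(zones$zone_grid, pv)
  cs <- zones$zone_grid$cellsize
  tab <- table(factor(pv[!is.na(pv)], levels = 1:3, labels = levels))
  areas <- data.frame(policy = names(tab),
                      area_km2 = as.numeric(tab) * cs^2 / 1e6)
  areas$percent <- 100 * areas$area_km2 / sum(areas$area_km2)
  structure(list(policy_grid = pg, areas = areas, mapping = mapping,
                 levels = levels),
            class = "esp_policy")
}

#' @export
print.esp_policy <- function(x, ...) {
  cat("esp_policy areas\n")
  print(x$areas, row.names = FALSE)
  invisible(x)
}
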