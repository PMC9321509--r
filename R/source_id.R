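patch_table <- function(labels, cellsize) {
  ids <- sort(unique(labels[labels > 0 & !is.na(labels)]))
  if (!length(ids))
    return(data.frame(id = integer(0), cells = integer(0),
                      area_km2 = numeric(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0)))
  rows <- row(labels); cols <- col(labels)
  do.call(rbind, lapply(ids, function(i) {
    sel <- which(labels == i)
    data.frame(id = i, cells = length(sel),
               area_km2 = length(sel) * cellsize^2 / 1e6,
               row_min = min(rows[sel]), row_max = max(rows[sel]),
               col_min = min(cols[sel]), col_max = max(cols[sel]))
  }))
}

new_patchset <- function(label_grid, cellsize) {
  structure(list(label_grid = label_grid,
                 patches = patch_table(label_grid$values, cellsize)),
            class = "esp_patches")
}

#' @export
print.esp_patches <- function(x, ...) {
  cat(sprintf("esp_patches: %d patch(es), total area %.3f km2\n",
              nrow(x$patches), sum(x$patches$area_km2)))
  invisible(x)
}

#' Label connected patches of a target class
#'
#' Connected-component labelling of all cells equal to `target_class`.
#' Default 8-connectivity (diagonal contact joins patches), the usual
#' convention for landscape patch delineation.
#'
#' @param class_grid integer-class [esp_grid()]
#' @param target_class class value to extract
#' @param connectivity 4 or 8
#' @return an object of class `esp_patches`: `label_grid` (0 = background,
#'   dense patch ids 1..P) and a `patches` table with cell counts and areas
#'   in km2. An absent class yields an empty patch set, not an error.
#' @export
label_patches <- function(class_grid, target_class, connectivity = 8) {
  stopifnot(is_esp_grid(class_grid))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- !is.na(class_grid$values) & class_grid$values == target_class
  lab <- cpp_label(mask, as.integer(connectivity))
  new_patchset(grid_like(class_grid, lab), class_grid$cellsize)
}

# Minimum cell-centre distance (metres) from every cell to each patch,
# evaluated pairwise via one distance transform per patch.
patch_pair_distances <- function(label_grid) {
  labels <- label_grid$values
  ids <- sort(unique(labels[labels > 0]))
  P <- length(ids)
  D <- matrix(Inf, P, P)
  diag(D) <- 0
  if (P < 2) return(D)
  for (a in seq_len(P - 1)) {
    edt <- cpp_edt(labels == ids[a], label_grid$cellsize)
    for (b in (a + 1):P) {
      d <- min(edt[labels == ids[b]])
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}

#' Merge patches separated by less than a gap distance
#'
#' Patches whose minimum edge-to-edge distance (between nearest cell
#' centres) is strictly less than `max_gap` metres are unioned transitively
#' (union-find over the pairwise predicate). Merged patches are multi-part:
#' the gap cells stay background, so areas are sums of member areas and are
#' not inflated. Idempotent, and monotone in `max_gap`.
#'
#' @param patches an `esp_patches` object
#' @param max_gap gap threshold in metres (strict `<`)
#' @return an `esp_patches` object with merged, densely relabelled patches
#' @export
merge_nearby <- function(patches, max_gap) {
  stopifnot(inherits(patches, "esp_patches"), max_gap >= 0)
  labels <- patches$label_grid$values
  ids <- sort(unique(labels[labels > 0]))
  P <- length(ids)
  if (P < 2) return(patches)
  D <- patch_pair_distances(patches$label_grid)
  # union-find
  parent <- seq_len(P)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(P - 1))
    for (b in (a + 1):P)
      if (D[a, b] < max_gap) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
  root <- vapply(seq_len(P), find, integer(1))
  new_id <- match(root, sort(unique(root)))  # dense, ordered by smallest member
  relab <- labels
  relab[labels > 0] <- new_id[match(labels[labels > 0], ids)]
  new_patchset(grid_like(patches$label_grid, relab),
               patches$label_grid$cellsize)
}

#' Filter patches by minimum area
#'
#' Keeps patches whose area is strictly greater than `min_area_km2` and
#' relabels them densely in order of descending area: these are the
#' ecological sources.
#'
#' @param patches an `esp_patches` object (typically after [merge_nearby()])
#' @param min_area_km2 area threshold in km2 (strict `>`)
#' @return an `esp_patches` object (the source set); empty with a warning if
#'   nothing passes
#' @export
filter_by_area <- function(patches, min_area_km2) {
  stopifnot(inherits(patches, "esp_patches"), min_area_km2 >= 0)
  keep <- patches$patches[patches$patches$area_km2 > min_area_km2, ]
  if (nrow(keep) == 0L) {
    warning("no patch exceeds the area threshold; source set is empty")
    lab <- patches$label_grid$values * 0L
    return(new_patchset(grid_like(patches$label_grid, lab),
                        patches$label_grid$cellsize))
  }
  keep <- keep[order(-keep$area_km2, keep$id), ]
  labels <- patches$label_grid$values
  relab <- matrix(0L, nrow(labels), ncol(labels))
  for (j in seq_len(nrow(keep)))
    relab[labels == keep$id[j]] <- j
  new_patchset(grid_like(patches$label_grid, relab),
               patches$label_grid$cellsize)
}

#' Land-use composition of the source set
#'
#' Tabulates, per land-use class, the area (km2) and the percentage of the
#' total source area covered by that class. Percentages sum to 100.
#'
#' @param sources an `esp_patches` object (the source set)
#' @param landuse aligned land-use class [esp_grid()]
#' @param class_names optional named character vector mapping codes to names
#' @return data.frame with `class`, `area_km2`, `percent`
#' @export
landuse_composition <- function(sources, landuse, class_names = NULL) {
  stopifnot(inherits(sources, "esp_patches"), is_esp_grid(landuse))
  check_aligned(sources$label_grid, landuse)
  sel <- sources$label_grid$values > 0
  lu <- landuse$values[sel]
  lu <- lu[!is.na(lu)]
  if (!length(lu))
    return(data.frame(class = numeric(0), area_km2 = numeric(0),
                      percent = numeric(0)))
  tab <- table(lu)
  cs <- sources$label_grid$cellsize
  out <- data.frame(class = as.numeric(names(tab)),
                    area_km2 = as.numeric(tab) * cs^2 / 1e6)
  out$percent <- 100 * out$area_km2 / sum(out$area_km2)
  if (!is.null(class_names))
    out$name <- unname(class_names[as.character(out$class)])
  out
}

#' Export source patches as GeoJSON
#'
#' Writes one MultiPolygon feature per source (one square ring per member
#' cell) with `id` and `area_km2` properties.
#'
#' @param sources an `esp_patches` object
#' @param path destination file
#' @export
export_sources_geojson <- function(sources, path) {
  g <- sources$label_grid
  cs <- g$cellsize; ox <- g$origin[1]; oy <- g$origin[2]
  feats <- lapply(seq_len(nrow(sources$patches)), function(j) {
    id <- sources$patches$id[j]
    sel <- which(g$values == id, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(sel)), function(i) {
      r <- sel[i, 1]; c <- sel[i, 2]
      x0 <- ox + (c - 1) * cs; x1 <- x0 + cs
      y1 <- oy - (r - 1) * cs; y0 <- y1 - cs
      list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(id = id,
                           area_km2 = sources$patches$area_km2[j]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
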