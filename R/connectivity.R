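resist_grid_of <- function(surface) {
  if (inherits(surface, "esp_resistance")) return(surface$grid)
  if (is_esp_grid(surface)) return(surface)
  stop("surface must be an esp_resistance or esp_grid")
}

source_labels_of <- function(sources, template) {
  if (inherits(sources, "esp_patches")) {
    check_aligned(sources$label_grid, template)
    return(sources$label_grid$values)
  }
  if (is_esp_grid(sources)) {
    check_aligned(sources, template)
    v <- sources$values
    v[is.na(v)] <- 0
    return(v)
  }
  if (is.logical(sources) && is.matrix(sources)) {
    m <- matrix(0L, nrow(template$values), ncol(template$values))
    m[which(sources)] <- 1L
    return(m)
  }
  if (is.matrix(sources) && ncol(sources) == 2L) {
    m <- matrix(0L, nrow(template$values), ncol(template$values))
    m[sources] <- 1L
    return(m)
  }
  stop("sources must be esp_patches, a label grid, a mask or (row, col) cells")
}

#' Minimum cumulative resistance (cost distance) from sources
#'
#' For every cell, the minimum cumulative resistance `sum(D_ij * R_i)`
#' accumulated along any path from the nearest ecological source, computed
#' by multi-source Dijkstra over the 8-connected cell graph. The step cost
#' between neighbours is the mean of their resistances times the step
#' length (cellsize, or cellsize * sqrt(2) diagonally). The monotone outer
#' transform of the MCR formulation is taken as the identity: any monotone
#' transform preserves the ranking of paths, so least-cost paths are
#' unchanged.
#'
#' @param surface `esp_resistance` (or resistance [esp_grid()]) with
#'   positive values; nodata cells are barriers
#' @param sources source regions: `esp_patches`, a label grid, logical
#'   mask or `(row, col)` matrix
#' @return object of class `esp_costdist`: `cost` grid (0 on sources, NA
#'   where unreachable), `allocation` grid of nearest-source id, and the
#'   predecessor matrix used for path backtracing
#' @export
cost_distance <- function(surface, sources) {
  rg <- resist_grid_of(surface)
  if (all(is.na(rg$values))) stop("resistance surface is all nodata")
  v <- rg$values[!is.na(rg$values)]
  if (any(v <= 0)) stop("resistance must be strictly positive")
  lab <- source_labels_of(sources, rg)
  if (!any(lab > 0, na.rm = TRUE)) stop("at least one source cell required")
  storage.mode(lab) <- "integer"
  res <- cpp_cost_distance(rg$values, lab, rg$cellsize)
  alloc <- res$allocation
  alloc[is.na(res$cost)] <- NA_integer_
  structure(list(cost = grid_like(rg, res$cost),
                 allocation = grid_like(rg, alloc),
                 pred = res$pred),
            class = "esp_costdist")
}

backtrace_path <- function(pred, nr, end_rc) {
  path <- list()
  r <- end_rc[1]; c <- end_rc[2]
  repeat {
    path[[length(path) + 1L]] <- c(r, c)
    p <- pred[r, c]
    if (p == 0L) break
    c <- (p - 1L) %/% nr + 1L
    r <- (p - 1L) %% nr + 1L
  }
  do.call(rbind, rev(path))
}

path_length_m <- function(path, cellsize) {
  if (is.null(path) || nrow(path) < 2L) return(0)
  steps <- diff(path)
  sum(sqrt(steps[, 1]^2 + steps[, 2]^2)) * cellsize
}

#' Least-cost path between two source regions
#'
#' The minimum-cost cell path from any cell of region `a` to any cell of
#' region `b` over the resistance surface (8-connected, mean-of-endpoints
#' step cost). Ties are broken deterministically (lexicographic by cost,
#' row, column). If the regions overlap the path is empty with zero cost;
#' if they are mutually unreachable the corridor is flagged `disconnected`.
#'
#' @param surface `esp_resistance` or resistance [esp_grid()]
#' @param source_a,source_b source regions (mask, label grid,
#'   `esp_patches`, or `(row, col)` matrix; for `esp_patches` supply the
#'   patch of interest via a mask `label_grid$values == id`)
#' @return object of class `esp_corridor`: `path` (n x 2 row/col matrix),
#'   `cost`, `length_m`, `disconnected`
#' @export
least_cost_path <- function(surface, source_a, source_b) {
  rg <- resist_grid_of(surface)
  la <- source_labels_of(source_a, rg)
  lb <- source_labels_of(source_b, rg)
  if (!any(la > 0) || !any(lb > 0)) stop("both source regions must be non-empty")
  if (any(la > 0 & lb > 0)) {
    return(structure(list(path = matrix(integer(0), 0, 2), cost = 0,
                          length_m = 0, disconnected = FALSE),
                     class = "esp_corridor"))
  }
  la[la > 0] <- 1L
  storage.mode(la) <- "integer"
  res <- cpp_cost_distance(rg$values, la, rg$cellsize)
  bcells <- which(lb > 0 & !is.na(res$cost))
  if (!length(bcells)) {
    return(structure(list(path = NULL, cost = NA_real_, length_m = NA_real_,
                          disconnected = TRUE), class = "esp_corridor"))
  }
  best <- bcells[which.min(res$cost[bcells])]
  nr <- nrow(rg$values)
  end_rc <- c((best - 1L) %% nr + 1L, (best - 1L) %/% nr + 1L)
  path <- backtrace_path(res$pred, nr, end_rc)
  structure(list(path = path, cost = res$cost[best],
                 length_m = path_length_m(path, rg$cellsize),
                 disconnected = FALSE),
            class = "esp_corridor")
}

#' @export
print.esp_corridor <- function(x, ...) {
  if (isTRUE(x$disconnected)) cat("esp_corridor: disconnected pair\n")
  else cat(sprintf("esp_corridor: cost %.4g, length %.4g m, %d cells\n",
                   x$cost, x$length_m, if (is.null(x$path)) 0 else nrow(x$path)))
  invisible(x)
}

#' Least-cost corridor network between ecological sources
#'
#' Builds one corridor per source pair. In `adjacent_pairs` mode (default),
#' a corridor is extracted only for pairs whose cost-allocation regions
#' share a cell edge (the core-area adjacency used by corridor-mapping
#' tools); `all_pairs` connects every pair. Disconnected pairs are reported
#' but carry no path.
#'
#' @param surface `esp_resistance` or resistance [esp_grid()]
#' @param sources `esp_patches` source set (>= 2 sources) or label grid
#' @param mode `"adjacent_pairs"` or `"all_pairs"`
#' @return list of class `esp_network`: `corridors` (list of
#'   `esp_corridor` with `a`, `b` source ids), `n_corridors`,
#'   `total_length_m`, and the `esp_costdist` used for allocation
#' @export
corridor_network <- function(surface, sources,
                             mode = c("adjacent_pairs", "all_pairs")) {
  mode <- match.arg(mode)
  rg <- resist_grid_of(surface)
  lab <- source_labels_of(sources, rg)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) < 2L) {
    warning("fewer than two sources; corridor network is empty")
    return(structure(list(corridors = list(), n_corridors = 0L,
                          total_length_m = 0, costdist = NULL),
                     class = "esp_network"))
  }
  cd <- cost_distance(surface, sources)
  pairs <- if (mode == "all_pairs") {
    utils::combn(ids, 2, simplify = FALSE)
  } else {
    al <- cd$allocation$values
    nr <- nrow(al); nc <- ncol(al)
    adj <- rbind(
      cbind(as.vector(al[-nr, ]), as.vector(al[-1, ])),   # vertical edges
      cbind(as.vector(al[, -nc]), as.vector(al[, -1])))   # horizontal edges
    adj <- adj[!is.na(adj[, 1]) & !is.na(adj[, 2]) & adj[, 1] != adj[, 2], ,
               drop = FALSE]
    if (nrow(adj)) {
      adj <- unique(t(apply(adj, 1, sort)))
      lapply(seq_len(nrow(adj)), function(i) adj[i, ])
    } else list()
  }
  corridors <- lapply(pairs, function(p) {
    co <- least_cost_path(surface, lab == p[1], lab == p[2])
    co$a <- p[1]; co$b <- p[2]
    co
  })
  ok <- vapply(corridors, function(co) !isTRUE(co$disconnected), logical(1))
  structure(list(corridors = corridors,
                 n_corridors = sum(ok),
                 total_length_m = sum(vapply(corridors[ok],
                                             function(co) co$length_m,
                                             numeric(1))),
                 costdist = cd),
            class = "esp_network")
}

#' @export
print.esp_network <- function(x, ...) {
  cat(sprintf("esp_network: %d corridor(s), total length %.4g m\n",
              x$n_corridors, x$total_length_m))
  invisible(x)
}

#' Circuit-theory current flow along a corridor
#'
#' Models the low-cost swath around a corridor as a resistive network and
#' solves for current flow between its two source regions: per-cell nodes,
#' edge conductance equal to the reciprocal of the Dijkstra step cost, the
#' source-a cells collapsed into a unit-current injection node and the
#' source-b cells grounded. The swath comprises the cells whose
#' cost-from-a plus cost-from-b is within `(1 + swath_percentile)` times
#' the corridor cost. Cell current is half the sum of absolute currents on
#' incident edges; bottleneck (pinch-point) cells carry concentrated
#' current.
#'
#' @param surface `esp_resistance` or resistance [esp_grid()]
#' @param source_a,source_b the corridor's two source regions (masks or
#'   label grids)
#' @param swath_percentile cost slack defining the swath (default 0.05)
#' @return an [esp_grid()] of current density (NA outside the swath), with
#'   attribute `"pair_cost"`; a disconnected pair yields an all-NA grid
#'   with attribute `"disconnected" = TRUE`
#' @export
current_flow <- function(surface, source_a, source_b,
                         swath_percentile = 0.05) {
  rg <- resist_grid_of(surface)
  la <- source_labels_of(source_a, rg)
  lb <- source_labels_of(source_b, rg)
  storage.mode(la) <- "integer"; storage.mode(lb) <- "integer"
  la[la > 0] <- 1L; lb[lb > 0] <- 1L
  resA <- cpp_cost_distance(rg$values, la, rg$cellsize)
  resB <- cpp_cost_distance(rg$values, lb, rg$cellsize)
  out_na <- grid_like(rg, matrix(NA_real_, nrow(rg$values), ncol(rg$values)))
  bc <- which(lb > 0 & !is.na(resA$cost))
  if (!length(bc)) {
    attr(out_na, "disconnected") <- TRUE
    return(out_na)
  }
  cab <- min(resA$cost[bc])
  tot <- resA$cost + resB$cost
  swath <- !is.na(tot) & tot <= cab * (1 + swath_percentile)
  swath <- swath | (la > 0) | (lb > 0)
  swath[is.na(rg$values)] <- FALSE

  nr <- nrow(swath); nc <- ncol(swath)
  # node numbering: ground (b) = 0, injection supernode (a) = 1, others 2..
  node <- matrix(NA_integer_, nr, nc)
  node[swath & lb > 0] <- 0L
  node[swath & lb == 0 & la > 0] <- 1L
  free <- which(swath & la == 0 & lb == 0)
  node[free] <- seq_along(free) + 1L
  if (!any(node == 1L, na.rm = TRUE)) {
    attr(out_na, "disconnected") <- TRUE
    return(out_na)
  }

  # cell-level edge list over the swath (8-connected)
  cells <- which(swath)
  rr <- (cells - 1L) %% nr + 1L
  cc <- (cells - 1L) %/% nr + 1L
  edges <- NULL
  sqrt2 <- sqrt(2)
  for (m in seq_len(4)) {  # half the neighbourhood: E, S, SE, SW
    dr <- c(0L, 1L, 1L, 1L)[m]; dc <- c(1L, 0L, 1L, -1L)[m]
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    i1 <- cells[ok]; i2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- swath[i2]
    i1 <- i1[ok2]; i2 <- i2[ok2]
    if (!length(i1)) next
    d <- if (dr != 0L && dc != 0L) rg$cellsize * sqrt2 else rg$cellsize
    g <- 1 / (0.5 * (rg$values[i1] + rg$values[i2]) * d)
    edges <- rbind(edges, cbind(i1, i2, g))
  }
  if (is.null(edges)) {
    attr(out_na, "disconnected") <- TRUE
    return(out_na)
  }
  n1 <- node[edges[, 1]]; n2 <- node[edges[, 2]]
  keep <- !(n1 == n2)            # drop intra-supernode edges
  e1 <- n1[keep]; e2 <- n2[keep]; eg <- edges[keep, 3]
  ec1 <- edges[keep, 1]; ec2 <- edges[keep, 2]

  nn <- max(node, na.rm = TRUE)  # number of non-ground nodes
  # graph Laplacian over non-ground nodes (ground rows/cols dropped)
  ij <- rbind(cbind(e1, e2), cbind(e2, e1))
  gg <- c(-eg, -eg)
  on_diag <- rbind(cbind(e1, e1), cbind(e2, e2))
  ij <- rbind(ij, on_diag)
  gg <- c(gg, eg, eg)
  sel <- ij[, 1] > 0 & ij[, 2] > 0
  L <- Matrix::sparseMatrix(i = ij[sel, 1], j = ij[sel, 2], x = gg[sel],
                            dims = c(nn, nn))
  rhs <- numeric(nn)
  rhs[1] <- 1
  volt <- tryCatch(as.vector(Matrix::solve(L, rhs)),
                   error = function(e) NULL)
  if (is.null(volt)) {
    attr(out_na, "disconnected") <- TRUE
    return(out_na)
  }
  vat <- function(nid) {          # ground nodes (id 0) sit at 0 V
    v <- numeric(length(nid))
    pos <- nid > 0L
    v[pos] <- volt[nid[pos]]
    v
  }
  icur <- abs(eg * (vat(e1) - vat(e2)))
  cur <- matrix(0, nr, nc)
  for (k in seq_along(icur)) {
    cur[ec1[k]] <- cur[ec1[k]] + icur[k]
    cur[ec2[k]] <- cur[ec2[k]] + icur[k]
  }
  cur <- cur / 2
  cur[!swath] <- NA_real_
  out <- grid_like(rg, cur)
  attr(out, "pair_cost") <- cab
  out
}

#' Extract ecological nodes (pinch points) from current maps
#'
#' Takes the cellwise maximum over the per-corridor current maps, splits
#' the positive-current cells into general and important classes by a
#' two-class Jenks natural break, labels the important-class patches and
#' retains those larger than `min_area_km2` as important ecological nodes.
#' A constant current field admits no split: everything stays general.
#'
#' @param currents list of current [esp_grid()]s (from [current_flow()])
#' @param min_area_km2 importance area threshold (default 1, strict `>`)
#' @return object of class `esp_nodes`: `current` (max-over-corridors
#'   grid), `important_nodes` and `general_nodes` (`esp_patches`)
#' @export
extract_nodes <- function(currents, min_area_km2 = 1) {
  currents <- Filter(function(g) !isTRUE(attr(g, "disconnected")), currents)
  if (!length(currents)) stop("need at least one connected current grid")
  do.call(check_aligned, currents)
  mx <- Reduce(function(a, b) grid_like(a, pmax(a$values, b$values, na.rm = TRUE)),
               currents)
  pos <- mx$values
  pos[!is.na(pos) & pos <= 0] <- NA_real_
  posv <- pos[!is.na(pos)]
  template <- grid_like(mx, pos)
  empty <- function() new_patchset(grid_like(mx, matrix(0L, nrow(mx$values),
                                                        ncol(mx$values))),
                                   mx$cellsize)
  if (!length(posv)) {
    return(structure(list(current = mx, important_nodes = empty(),
                          general_nodes = empty()), class = "esp_nodes"))
  }
  if (length(unique(posv)) < 2L) {
    gen <- label_patches(grid_like(mx, ifelse(is.na(pos), NA, 1)), 1)
    return(structure(list(current = mx, important_nodes = empty(),
                          general_nodes = gen), class = "esp_nodes"))
  }
  br <- jenks_breaks(posv, 2)
  cls <- classify(template, br)
  important <- label_patches(cls, 2)
  important <- filter_by_area_quiet(important, min_area_km2)
  general <- label_patches(cls, 1)
  structure(list(current = mx, important_nodes = important,
                 general_nodes = general), class = "esp_nodes")
}

filter_by_area_quiet <- function(patches, min_area_km2) {
  suppressWarnings(filter_by_area(patches, min_area_km2))
}

#' Export corridors as GeoJSON LineStrings
#'
#' One feature per connected corridor with `source_a`, `source_b`, `cost`
#' and `length_m` properties; coordinates are cell centres in map units.
#'
#' @param network an `esp_network`
#' @param grid the [esp_grid()] template the corridors were computed on
#' @param path destination file
#' @export
export_corridors_geojson <- function(network, grid, path) {
  cs <- grid$cellsize; ox <- grid$origin[1]; oy <- grid$origin[2]
  ok <- Filter(function(co) !isTRUE(co$disconnected) && !is.null(co$path) &&
                 nrow(co$path) > 0, network$corridors)
  feats <- lapply(ok, function(co) {
    xy <- cbind(ox + (co$path[, 2] - 0.5) * cs,
                oy - (co$path[, 1] - 0.5) * cs)
    list(type = "Feature",
         properties = list(source_a = co$a, source_b = co$b,
                           cost = co$cost, length_m = co$length_m),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(xy)),
                                              function(i) xy[i, ])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
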