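# Independent oracles used to cross-check the implementation. These are
# deliberately naive (iterative relaxation, exhaustive enumeration, dense
# solves) and share no code with the package internals.

# Shortest cumulative-resistance cost by Bellman-style relaxation over the
# 8-connected cell graph; step cost = mean endpoint resistance * distance.
oracle_cost <- function(resist, cellsize, src_mask) {
  nr <- nrow(resist); nc <- ncol(resist)
  cost <- matrix(Inf, nr, nc)
  cost[src_mask & !is.na(resist)] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(resist[r, c])) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(resist[r2, c2])) next
        d <- cellsize * sqrt(dr^2 + dc^2)
        cand <- cost[r2, c2] + (resist[r, c] + resist[r2, c2]) / 2 * d
        if (cand < cost[r, c] - 1e-12) { cost[r, c] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  cost[!is.finite(cost)] <- NA
  cost
}

# Exhaustive enumeration of all contiguous k-partitions of sorted values;
# returns the minimal total within-class sum of squared deviations.
oracle_jenks_ssd <- function(x, k) {
  x <- sort(x); n <- length(x)
  ssd1 <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd1(x))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    s <- sum(vapply(seq_len(k), function(i) ssd1(x[(b[i] + 1):b[i + 1]]),
                    numeric(1)))
    if (s < best) best <- s
  }
  best
}

# total within-class SSD of a given classification of x
partition_ssd <- function(x, cls) {
  sum(vapply(split(x, cls), function(v) sum((v - mean(v))^2), numeric(1)))
}

# Flood-fill connected-component count over a logical mask.
oracle_component_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  moves <- if (connectivity == 8) {
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ]
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    count <- count + 1L
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (m in seq_len(nrow(moves))) {
        r2 <- cur[1] + moves[m, 1]; c2 <- cur[2] + moves[m, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  count
}

# Dense resistive-network solve for current flow between two regions on a
# full (unrestricted) grid: supernode injection at `amask`, ground at
# `bmask`, conductance = 1 / (mean endpoint resistance * step length).
# Returns per-cell current (half the sum of absolute incident edge currents).
oracle_current <- function(resist, cellsize, amask, bmask) {
  nr <- nrow(resist); nc <- ncol(resist)
  ok <- !is.na(resist)
  node <- matrix(NA_integer_, nr, nc)
  node[ok & bmask] <- 0L
  node[ok & amask & !bmask] <- 1L
  freec <- which(ok & !amask & !bmask)
  node[freec] <- seq_along(freec) + 1L
  nn <- max(node, na.rm = TRUE)
  L <- matrix(0, nn, nn)
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!ok[r, c]) next
    for (m in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r2 <- r + m[1]; c2 <- c + m[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !ok[r2, c2]) next
      d <- cellsize * sqrt(sum(m^2))
      g <- 1 / ((resist[r, c] + resist[r2, c2]) / 2 * d)
      n1 <- node[r, c]; n2 <- node[r2, c2]
      if (n1 == n2) next
      edges[[length(edges) + 1L]] <- list(i1 = (c - 1) * nr + r,
                                          i2 = (c2 - 1) * nr + r2,
                                          n1 = n1, n2 = n2, g = g)
      if (n1 > 0) L[n1, n1] <- L[n1, n1] + g
      if (n2 > 0) L[n2, n2] <- L[n2, n2] + g
      if (n1 > 0 && n2 > 0) {
        L[n1, n2] <- L[n1, n2] - g
        L[n2, n1] <- L[n2, n1] - g
      }
    }
  }
  rhs <- numeric(nn); rhs[1] <- 1
  volt <- solve(L, rhs)
  vat <- function(n) if (n == 0) 0 else volt[n]
  cur <- matrix(0, nr, nc)
  for (e in edges) {
    icur <- abs(e$g * (vat(e$n1) - vat(e$n2)))
    cur[e$i1] <- cur[e$i1] + icur
    cur[e$i2] <- cur[e$i2] + icur
  }
  cur <- cur / 2
  cur[!ok] <- NA
  cur
}

# convenience: grid from matrix at given cellsize
gm <- function(m, cellsize = 100) esp_grid(m, cellsize = cellsize)
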