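# Independent reference implementations used as test oracles. These are
# deliberately naive (queue flood fill, O(V^2) Dijkstra, explicit double
# sums) and share no code with the package internals.

# Flood-fill connected-component labelling of cells bearing classCodes.
# Returns a list of sorted linear (column-major) index vectors, ordered by
# smallest index.
oracleFloodFill <- function(m, classCodes, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  inClass <- matrix(m %in% classCodes, nr, nc)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  comps <- list()
  for (start in which(inClass & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      r <- ((cur - 1) %% nr) + 1
      c <- ((cur - 1) %/% nr) + 1
      for (o in offs) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        j <- r2 + (c2 - 1) * nr
        if (inClass[j] && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(vapply(comps, min, 0))]
}

# Plain O(V^2) Dijkstra over the 8-connected cell lattice with edge cost
# step * cellSize * (1 + (r_u + r_v)/2); step = sqrt(2) on diagonals.
# sources/targets are linear column-major indices; returns min distance.
oracleLeastCost <- function(resist, cellSize, sources, targets) {
  nr <- nrow(resist); nc <- ncol(resist)
  n <- nr * nc
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    r <- ((u - 1) %% nr) + 1
    c <- ((u - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- r2 + (c2 - 1) * nr
      step <- if (dr != 0 && dc != 0) sqrt(2) else 1
      w <- step * cellSize * (1 + (resist[u] + resist[v]) / 2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
    if (all(done[targets])) break
  }
  min(dist[targets])
}

# Explicit double-sum equivalent connected area.
oracleECA <- function(areas, p) {
  total <- 0
  for (x in seq_along(areas)) {
    for (y in seq_along(areas)) {
      total <- total + areas[x] * areas[y] * p[x, y]
    }
  }
  sqrt(total)
}

# Definitional Spearman: Pearson product-moment formula applied to average
# ranks, written out explicitly.
oracleSpearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Random symmetric pairwise-probability matrix with unit diagonal.
randomProbMatrix <- function(n) {
  p <- matrix(runif(n * n), n, n)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  p
}
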