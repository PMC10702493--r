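#' Build a land-cover legend
#'
#' Maps integer raster codes to (land use, intensity) classes. Intensity is
#' one of `"minimal"`, `"light"`, `"intense"` for anthropogenic classes,
#' `"natural"` for the natural-habitat reference class, or `"all"` for
#' classes pooled across intensities.
#'
#' @param code integer vector of raster codes.
#' @param land_use character vector of land-use names ("natural" for the
#'   reference class).
#' @param intensity character vector of intensity levels.
#' @return data.frame with columns code, land_use, intensity.
#' @examples
#' makeLegend(0:2, c("natural", "cropland", "cropland"),
#'            c("natural", "minimal", "intense"))
#' @export
makeLegend <- function(code, land_use, intensity) {
  stopifnot(length(code) == length(land_use),
            length(code) == length(intensity))
  ok <- intensity %in% c(.INTENSITY_LEVELS, .NATURAL, "all")
  if (!all(ok)) {
    stop("unknown intensity level(s): ",
         paste(unique(intensity[!ok]), collapse = ", "))
  }
  if (anyDuplicated(code)) stop("duplicated raster codes in legend")
  data.frame(code = as.integer(code), land_use = as.character(land_use),
             intensity = as.character(intensity), stringsAsFactors = FALSE)
}

.legendCodes <- function(legend, landUse, intensity) {
  codes <- legend$code[legend$land_use == landUse &
                       legend$intensity == intensity]
  if (!length(codes)) {
    stop("class (", landUse, ", ", intensity, ") not in legend")
  }
  codes
}

.checkCodes <- function(grid, legend) {
  present <- unique(as.vector(codes(grid)))
  present <- present[present != nodataCode(grid)]
  bad <- setdiff(present, legend$code)
  if (length(bad)) {
    stop("raster codes not in legend: ", paste(sort(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# Neighbour offsets (half set, scanning forward) for 4- or 8-connectivity.
.offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(0L, 1L), dc = c(1L, 0L))
  } else if (connectivity == 8) {
    cbind(dr = c(0L, 1L, 1L, 1L), dc = c(1L, 0L, 1L, -1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

# Edge list between cells of a logical mask, as linear (column-major) indices.
.maskEdges <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  off <- .offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- r + off[k, "dr"]; c2 <- c + off[k, "dc"]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- r2[ok] + (c2[ok] - 1L) * nr
    keep <- mask[j]
    from <- c(from, idx[ok][keep])
    to <- c(to, j[keep])
  }
  cbind(from, to)
}

#' Extract connected patches of one land-use class
#'
#' Labels the connected components of all cells bearing the codes of a given
#' (land use, intensity) class. Patch ids follow row-major scan order of each
#' patch's first cell, so labelling is deterministic.
#'
#' @param grid a [LandscapeGrid-class].
#' @param legend legend data.frame (see [makeLegend()]).
#' @param landUse,intensity the class to extract.
#' @param connectivity 4 or 8 (default 8: diagonal cells touch).
#' @return A list of patches; each patch is a list with elements `id`,
#'   `land_use`, `intensity`, `cells` (two-column matrix of row, col),
#'   `area` (m^2) and `boundary` (two-column matrix of boundary cells).
#' @examples
#' leg <- makeLegend(0:1, c("natural", "cropland"), c("natural", "minimal"))
#' m <- matrix(0L, 5, 5); m[2:3, 2:3] <- 1L
#' g <- landscapeGrid(m, 1000, "eco1")
#' length(extractPatches(g, leg, "cropland", "minimal"))
#' @export
extractPatches <- function(grid, legend, landUse, intensity,
                           connectivity = 8) {
  .checkCodes(grid, legend)
  classCodes <- .legendCodes(legend, landUse, intensity)
  m <- codes(grid)
  nr <- nrow(m); nc <- ncol(m)
  mask <- matrix(m %in% classCodes, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(list())
  vid <- match(seq_len(nr * nc), idx)  # linear index -> vertex id
  edges <- .maskEdges(mask, connectivity)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(vid[edges[, 1]], vid[edges[, 2]]))
  }
  memb <- igraph::components(g)$membership
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  scan <- (r - 1L) * nc + c  # row-major scan order
  firstScan <- tapply(scan, memb, min)
  newId <- match(memb, as.integer(names(sort(firstScan))))
  cs <- cellSize(grid)
  lapply(sort(unique(newId)), function(id) {
    sel <- newId == id
    cells <- cbind(row = r[sel], col = c[sel])
    o <- order(cells[, 1], cells[, 2])
    cells <- cells[o, , drop = FALSE]
    list(id = id, land_use = landUse, intensity = intensity,
         cells = cells, area = nrow(cells) * cs^2,
         boundary = .boundaryCells(cells, nr, nc))
  })
}

# Cells of a patch with at least one 4-neighbour outside the patch (or on the
# grid edge). Edge-to-edge distances are measured between these cell centres.
.boundaryCells <- function(cells, nr, nc) {
  key <- cells[, 1] + (cells[, 2] - 1) * nr
  inPatch <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- logical(length(r))
    out[ok] <- (r[ok] + (c[ok] - 1) * nr) %in% key
    out
  }
  interior <- inPatch(cells[, 1] - 1, cells[, 2]) &
    inPatch(cells[, 1] + 1, cells[, 2]) &
    inPatch(cells[, 1], cells[, 2] - 1) &
    inPatch(cells[, 1], cells[, 2] + 1)
  cells[!interior, , drop = FALSE]
}

# Lattice graph over passable cells with per-cell traversal cost
# cellSize * (1 + r); an edge costs the step length times the mean of the two
# cells' unit costs (sqrt(2) steps for diagonals).
.latticeGraph <- function(grid, resistance) {
  m <- codes(grid)
  nr <- nrow(m); nc <- ncol(m)
  passable <- matrix(m != nodataCode(grid), nr, nc)
  if (any(dim(resistance) != c(nr, nc))) {
    stop("resistance map must match the grid dimensions")
  }
  if (any(resistance < 0 | resistance > 1, na.rm = TRUE)) {
    stop("resistance values must lie in [0, 1]")
  }
  edges <- .maskEdges(passable, 8)
  r1 <- ((edges[, 1] - 1L) %% nr) + 1L
  r2 <- ((edges[, 2] - 1L) %% nr) + 1L
  c1 <- ((edges[, 1] - 1L) %/% nr) + 1L
  c2 <- ((edges[, 2] - 1L) %/% nr) + 1L
  step <- ifelse(r1 != r2 & c1 != c2, sqrt(2), 1)
  unit <- cellSize(grid) * (1 + resistance)
  w <- step * (unit[edges[, 1]] + unit[edges[, 2]]) / 2
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges[, 1], edges[, 2]))
  igraph::E(g)$weight <- w
  g
}

.linIdx <- function(cells, nr) cells[, 1] + (cells[, 2] - 1) * nr

#' Effective distance between two patches
#'
#' Without a resistance map: the minimum edge-to-edge Euclidean distance
#' between boundary-cell centres. With a resistance map: the least-cost
#' distance over the 8-connected cell graph, where traversing a cell costs
#' `cellSize * (1 + r)` (diagonal steps scaled by sqrt(2)); natural habitat
#' has r = 0 so the r = 0 limit recovers the grid path metric.
#'
#' @param a,b patches from [extractPatches()] (must not overlap).
#' @param grid the [LandscapeGrid-class] both patches live on.
#' @param resistance optional per-cell resistance matrix in \[0, 1\].
#' @return Effective distance in metres (symmetric, >= 0).
#' @export
patchDistance <- function(a, b, grid, resistance = NULL) {
  nr <- nrow(codes(grid))
  if (length(intersect(.linIdx(a$cells, nr), .linIdx(b$cells, nr)))) {
    stop("patches overlap")
  }
  if (is.null(resistance)) {
    .euclidMin(a$boundary, b$boundary, cellSize(grid))
  } else {
    g <- .latticeGraph(grid, resistance)
    d <- igraph::distances(g, v = .linIdx(a$boundary, nr),
                           to = .linIdx(b$boundary, nr))
    min(d)
  }
}

.euclidMin <- function(cellsA, cellsB, cs) {
  # boundary-cell centres in metres
  ax <- (cellsA[, 2] - 0.5) * cs; ay <- (cellsA[, 1] - 0.5) * cs
  bx <- (cellsB[, 2] - 0.5) * cs; by <- (cellsB[, 1] - 0.5) * cs
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  sqrt(min(d2))
}

# All pairwise effective distances among the patches of one class.
.patchPairDistances <- function(patches, grid, resistance = NULL) {
  n <- length(patches)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  if (is.null(resistance)) {
    cs <- cellSize(grid)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- .euclidMin(patches[[i]]$boundary,
                                         patches[[j]]$boundary, cs)
      }
    }
  } else {
    nr <- nrow(codes(grid))
    g <- .latticeGraph(grid, resistance)
    bnd <- lapply(patches, function(p) .linIdx(p$boundary, nr))
    all <- unlist(bnd)
    block <- rep(seq_len(n), vapply(bnd, length, 1L))
    dd <- igraph::distances(g, v = all, to = all)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- min(dd[block == i, block == j])
      }
    }
  }
  d
}

#' Dispersal probability between patches
#'
#' Negative-exponential kernel parameterized by the median dispersal
#' distance: `p = 2^(-d/dMed)`, so p(0) = 1 and p(dMed) = 0.5, strictly
#' decreasing to 0.
#'
#' @param d effective distance(s) in metres (>= 0).
#' @param dMed median dispersal distance in metres (> 0).
#' @return Probabilities in \[0, 1\].
#' @examples
#' dispersalProbability(c(0, 9000, 18000), dMed = 9000)
#' @export
dispersalProbability <- function(d, dMed) {
  if (any(d < 0)) stop("effective distance must be >= 0")
  if (length(dMed) != 1 || dMed <= 0) {
    stop("median dispersal distance must be a single positive number")
  }
  2^(-d / dMed)
}

# Pairwise probability matrix with small-probability cutoff; within-patch
# connectivity is perfect (diagonal 1).
.pairProbability <- function(distMat, dMed, cutoff = 1e-6) {
  p <- dispersalProbability(distMat, dMed)
  p[p < cutoff] <- 0
  diag(p) <- 1
  p
}

#' Equivalent connected area
#'
#' The area of a single patch with the same probability of connectivity as
#' the actual patch mosaic: `ECA = sqrt(sum_x sum_y A_x A_y p_xy)`. Equals
#' the total class area when all patches are fully connected and approaches
#' the largest single patch when fully disconnected.
#'
#' @param patches list of patches from [extractPatches()], or a numeric
#'   vector of patch areas in m^2.
#' @param p symmetric pairwise dispersal-probability matrix with unit
#'   diagonal and entries in \[0, 1\].
#' @return ECA in m^2.
#' @examples
#' equivalentConnectedArea(c(1e6, 1e6), matrix(c(1, 0, 0, 1), 2))
#' @export
equivalentConnectedArea <- function(patches, p) {
  a <- if (is.numeric(patches)) patches
       else vapply(patches, function(x) x$area, 0)
  if (!is.matrix(p) || nrow(p) != length(a) || ncol(p) != length(a)) {
    stop("probability matrix does not match the number of patches")
  }
  if (max(abs(p - t(p))) > 1e-12) stop("probability matrix must be symmetric")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(diag(p) - 1) > 1e-12)) stop("diagonal of p must be 1")
  sqrt(drop(crossprod(a, p %*% a)))
}

#' Per-class area and equivalent connected area
#'
#' Summarizes a landscape into one row per (land use, intensity) class
#' present (including natural habitat) with its total area A and its ECA
#' under the given dispersal kernel and, optionally, a class-specific
#' landscape resistance.
#'
#' @param grid a [LandscapeGrid-class].
#' @param legend legend data.frame.
#' @param dMed median dispersal distance (m) of the species group.
#' @param resistanceFor `NULL` (Euclidean separations) or a function
#'   `(landUse, intensity) -> resistance matrix` giving, for each habitat
#'   class, the per-cell resistance of the surrounding landscape.
#' @param connectivity patch neighbourhood rule, 4 or 8.
#' @param cutoff pairwise probabilities below this are treated as 0.
#' @param fragmentation if `FALSE`, ECA is replaced by the total class area
#'   (the no-fragmentation variant).
#' @return data.frame: land_use, intensity, A, ECA (m^2; ECA <= A).
#' @export
classConnectivity <- function(grid, legend, dMed, resistanceFor = NULL,
                              connectivity = 8, cutoff = 1e-6,
                              fragmentation = TRUE) {
  .checkCodes(grid, legend)
  m <- codes(grid)
  present <- unique(as.vector(m))
  present <- present[present != nodataCode(grid)]
  cls <- unique(legend[legend$code %in% present, c("land_use", "intensity")])
  cls <- cls[order(cls$land_use, cls$intensity), , drop = FALSE]
  out <- lapply(seq_len(nrow(cls)), function(k) {
    lu <- cls$land_use[k]; int <- cls$intensity[k]
    patches <- extractPatches(grid, legend, lu, int, connectivity)
    A <- sum(vapply(patches, function(p) p$area, 0))
    if (!fragmentation || length(patches) == 1L) {
      eca <- A
    } else {
      res <- if (is.null(resistanceFor)) NULL else resistanceFor(lu, int)
      d <- .patchPairDistances(patches, grid, res)
      p <- .pairProbability(d, dMed, cutoff)
      eca <- equivalentConnectedArea(patches, p)
    }
    data.frame(land_use = lu, intensity = int, A = A, ECA = eca,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
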