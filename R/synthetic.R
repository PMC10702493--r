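#' Specification of a synthetic study system
#'
#' Describes the synthetic world the generator builds: the ecoregion
#' mosaic, grid geometry, land-use class mix, fragmentation level, species
#' groups and the ranges the parameter tables are drawn from. The seed
#' fixes all randomness; each generator derives its stream from it, so the
#' same spec always yields byte-identical artifacts.
#'
#' @param nEcoregions number of ecoregions.
#' @param dim c(rows, cols) of each ecoregion's raster.
#' @param cellSize cell edge in metres.
#' @param nBiomes number of biomes (ecoregions assigned round-robin).
#' @param nCountries number of countries in the overlay.
#' @param landUses named list: land use -> character vector of intensity
#'   levels (subset of minimal/light/intense).
#' @param anthroShare total share of anthropogenic land per ecoregion
#'   (the rest stays natural habitat).
#' @param phi fragmentation parameter in \[0, 1\]: 0 grows each class as a
#'   single patch, 1 scatters its cells independently.
#' @param groups data.frame group, kingdom.
#' @param rrMinimalRange,rrDecayRange uniform ranges for the richness of
#'   minimal-intensity classes and the multiplicative decay per intensity
#'   step (keeps rr(minimal) >= rr(light) >= rr(intense)).
#' @param seRange uniform range of richness standard errors (wide enough
#'   that some intensity pairs merge under the 0.05 rule and some do not).
#' @param zRange uniform range of species-area slopes.
#' @param dispersalRanges named list: group -> c(lo, hi) median dispersal
#'   in metres; amphibians and reptiles are fixed at `constantDispersal`.
#' @param constantDispersal dispersal distance (m) for amphibians/reptiles.
#' @param seed integer seed.
#' @return A list of class "WorldSpec".
#' @export
worldSpec <- function(nEcoregions = 4,
                      dim = c(30, 30),
                      cellSize = 1000,
                      nBiomes = 2,
                      nCountries = 3,
                      landUses = list(
                        cropland = c("minimal", "light", "intense"),
                        pasture = c("minimal", "light", "intense"),
                        plantation = c("minimal", "intense"),
                        managed_forest = c("minimal", "light", "intense"),
                        urban = c("light", "intense")),
                      anthroShare = 0.4,
                      phi = 0.3,
                      groups = data.frame(
                        group = c("plants", "birds", "mammals",
                                  "amphibians", "reptiles"),
                        kingdom = c("plant", "animal", "animal",
                                    "animal", "animal"),
                        stringsAsFactors = FALSE),
                      rrMinimalRange = c(0.55, 0.95),
                      rrDecayRange = c(0.65, 0.95),
                      seRange = c(0.02, 0.12),
                      zRange = c(0.15, 0.35),
                      dispersalRanges = list(
                        plants = c(300, 3000),
                        birds = c(8000, 40000),
                        mammals = c(3000, 20000)),
                      constantDispersal = 9000,
                      seed = 1L) {
  if (anthroShare < 0 || anthroShare > 1) {
    stop("anthroShare must lie in [0, 1]")
  }
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  spec <- list(nEcoregions = nEcoregions, dim = dim, cellSize = cellSize,
               nBiomes = nBiomes, nCountries = nCountries,
               landUses = landUses, anthroShare = anthroShare, phi = phi,
               groups = groups, rrMinimalRange = rrMinimalRange,
               rrDecayRange = rrDecayRange, seRange = seRange,
               zRange = zRange, dispersalRanges = dispersalRanges,
               constantDispersal = constantDispersal,
               seed = as.integer(seed))
  class(spec) <- "WorldSpec"
  spec
}

#' Legend of a synthetic world
#'
#' Code 0 is natural habitat; anthropogenic classes are enumerated in the
#' order of the spec's land-use list.
#'
#' @param spec a [worldSpec()].
#' @return Legend data.frame (code, land_use, intensity).
#' @export
worldLegend <- function(spec) {
  lu <- rep(names(spec$landUses),
            vapply(spec$landUses, length, 1L))
  int <- unlist(spec$landUses, use.names = FALSE)
  makeLegend(c(0L, seq_along(lu)), c(.NATURAL, lu), c(.NATURAL, int))
}

.ecoIds <- function(spec) paste0("eco", seq_len(spec$nEcoregions))
.biomeOf <- function(spec) {
  paste0("biome", rep_len(seq_len(spec$nBiomes), spec$nEcoregions))
}

# 8-neighbour linear indices of a cell set within an nr x nc grid.
.neighbours8 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, r2[ok] + (c2[ok] - 1L) * nr)
  }
  unique(out)
}

# Seeded cluster growth: claim n free cells for one class with nSeeds
# accretion nuclei; phi = 0 gives one nucleus (a single connected patch),
# phi = 1 gives n nuclei (independent scatter).
.growClass <- function(free, n, nSeeds, nr, nc) {
  claimed <- integer(0)
  if (nSeeds >= n) {
    freeIdx <- which(free)
    if (length(freeIdx) < n) stop("landscape full: infeasible class shares")
    return(freeIdx[sample.int(length(freeIdx), n)])
  }
  remaining <- n
  seedsLeft <- nSeeds
  while (remaining > 0) {
    freeIdx <- which(free)
    if (!length(freeIdx)) stop("landscape full: infeasible class shares")
    seed <- if (length(freeIdx) == 1L) freeIdx else sample(freeIdx, 1)
    quota <- ceiling(remaining / max(seedsLeft, 1))
    region <- seed
    free[seed] <- FALSE
    frontier <- .neighbours8(seed, nr, nc)
    frontier <- frontier[free[frontier]]
    while (length(region) < quota && length(frontier)) {
      nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1)
      region <- c(region, nxt)
      free[nxt] <- FALSE
      nb <- .neighbours8(nxt, nr, nc)
      frontier <- unique(c(frontier[frontier != nxt], nb[free[nb]]))
    }
    claimed <- c(claimed, region)
    remaining <- remaining - length(region)
    seedsLeft <- max(seedsLeft - 1, 1)
  }
  claimed
}

#' Generate one synthetic landscape
#'
#' Builds the categorical raster of one ecoregion by seeded cluster growth:
#' every anthropogenic class receives its target cell count (round(share x
#' cells), exact), placed with a number of accretion nuclei controlled by
#' the fragmentation parameter phi. Remaining cells are natural habitat.
#'
#' @param spec a [worldSpec()].
#' @param ecoregion ecoregion index (1-based) or id like "eco2".
#' @return A [LandscapeGrid-class].
#' @export
genLandscape <- function(spec, ecoregion = 1) {
  i <- if (is.character(ecoregion)) {
    match(ecoregion, .ecoIds(spec))
  } else {
    as.integer(ecoregion)
  }
  if (is.na(i) || i < 1 || i > spec$nEcoregions) stop("unknown ecoregion")
  set.seed(spec$seed + 7919L * i)
  legend <- worldLegend(spec)
  anthro <- legend[legend$land_use != .NATURAL, , drop = FALSE]
  nr <- spec$dim[1]; nc <- spec$dim[2]
  N <- nr * nc
  w <- runif(nrow(anthro), 0.5, 1.5)
  shares <- spec$anthroShare * w / sum(w)
  targets <- round(shares * N)
  if (sum(targets) > N) stop("infeasible class shares")
  m <- matrix(0L, nr, nc)
  free <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(anthro))) {
    n <- targets[k]
    if (n == 0) next
    nSeeds <- max(1L, min(n, as.integer(round(1 + spec$phi * (n - 1)))))
    cells <- .growClass(free, n, nSeeds, nr, nc)
    m[cells] <- anthro$code[k]
    free[cells] <- FALSE
  }
  landscapeGrid(m, spec$cellSize, .ecoIds(spec)[i])
}

#' Generate the biological parameter tables
#'
#' Draws an internally consistent [ParamSet-class]: richness tables with
#' rr(minimal) >= rr(light) >= rr(intense) within each land use and
#' uncertainty wide enough to exercise intensity merging both ways;
#' biome-specific z-values; per-ecoregion median dispersal distances (with
#' the configured amphibian/reptile constant); vertebrate suitability and
#' shared-species counts; regeneration times; and normalized GEPs.
#'
#' @param spec a [worldSpec()].
#' @return A [ParamSet-class].
#' @export
genParams <- function(spec) {
  set.seed(spec$seed + 101L)
  groups <- spec$groups
  ecoIds <- .ecoIds(spec)
  biomes <- paste0("biome", seq_len(spec$nBiomes))
  legend <- worldLegend(spec)
  anthro <- legend[legend$land_use != .NATURAL, , drop = FALSE]
  landUses <- unique(anthro$land_use)

  rr <- list()
  for (g in groups$group) {
    for (lu in names(spec$landUses)) {
      levels <- spec$landUses[[lu]]
      val <- runif(1, spec$rrMinimalRange[1], spec$rrMinimalRange[2])
      for (int in levels) {
        se <- runif(1, spec$seRange[1], spec$seRange[2])
        rr[[length(rr) + 1]] <- data.frame(
          group = g, land_use = lu, intensity = int, rr = val, se = se,
          lo = max(0.01, val - 1.96 * se), hi = val + 1.96 * se,
          stringsAsFactors = FALSE)
        val <- val * runif(1, spec$rrDecayRange[1], spec$rrDecayRange[2])
      }
    }
  }
  rr <- do.call(rbind, rr)

  z <- expand.grid(group = groups$group, biome = biomes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z$z <- runif(nrow(z), spec$zRange[1], spec$zRange[2])

  dispersal <- expand.grid(group = groups$group, ecoregion = ecoIds,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dispersal$d_med <- NA_real_
  for (i in seq_len(nrow(dispersal))) {
    g <- dispersal$group[i]
    rng <- spec$dispersalRanges[[g]]
    dispersal$d_med[i] <- if (is.null(rng)) {
      spec$constantDispersal
    } else {
      runif(1, rng[1], rng[2])
    }
  }

  vertGroups <- groups$group[groups$kingdom == "animal"]
  suit <- list(); shared <- list()
  for (g in vertGroups) {
    for (eco in ecoIds) {
      sTotal <- sample(80:400, 1)
      sBy <- setNames(round(sTotal * runif(length(landUses), 0.25, 0.9)),
                      landUses)
      for (lu in landUses) {
        suit[[length(suit) + 1]] <- data.frame(
          group = g, ecoregion = eco, land_use = lu, S = sBy[[lu]],
          S_total = sTotal, stringsAsFactors = FALSE)
      }
      habs <- c(.NATURAL, landUses)
      for (hab in habs) {
        sHab <- if (hab == .NATURAL) sTotal else sBy[[hab]]
        for (sur in landUses) {
          if (sur == hab) next
          shared[[length(shared) + 1]] <- data.frame(
            group = g, ecoregion = eco, habitat_land_use = hab,
            surrounding_land_use = sur,
            S_shared = round(sHab * runif(1, 0.3, 0.95)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  regen <- expand.grid(group = groups$group, biome = biomes,
                       land_use = landUses,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  regen$t_reg <- runif(nrow(regen), 25, 150)

  paramSet(rr = rr, z = z, dispersal = dispersal,
           suitability = if (length(suit)) do.call(rbind, suit)
                         else data.frame(),
           shared = if (length(shared)) do.call(rbind, shared)
                    else data.frame(),
           regeneration = regen, geps = genGEPs(spec), groups = groups)
}

#' Generate global extinction probabilities
#'
#' Draws positive endemism scores per (group, ecoregion) and normalizes
#' them so that each species group's GEPs sum to exactly 1 over all
#' ecoregions.
#'
#' @param spec a [worldSpec()].
#' @return data.frame group, ecoregion, gep.
#' @export
genGEPs <- function(spec) {
  set.seed(spec$seed + 202L)
  ecoIds <- .ecoIds(spec)
  out <- expand.grid(group = spec$groups$group, ecoregion = ecoIds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$gep <- runif(nrow(out), 0.05, 1)
  for (g in unique(out$group)) {
    sel <- out$group == g
    out$gep[sel] <- out$gep[sel] / sum(out$gep[sel])
  }
  out
}

# Threat-record templates: threat_codes, criteria, category and the planted
# truth of whether the species passes the land-use threat filter.
.THREAT_TEMPLATES <- data.frame(
  category = c("EN", "VU", "CR", "LC", "NT", "DD", "EN", "VU", "EN",
               "EX", "EW", "VU", "EN", "VU"),
  threat_codes = c("2.1", "1.1", "2.2.1", "2.1", "1", "2.3", "5.1;3.2",
                   "1", "2.3", "2.1", "2.2", "12.1", "2.4", "2.1.2"),
  criteria = c("A2c", "B1ab(iii)", "A1a; A2d", "A2c", "A2c", "",
               "A2c", "A1d; A4e", "A2de", "A2cd", "D", "A2c", "A2c",
               "A2b"),
  qualifies = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

#' Generate synthetic Red List threat records
#'
#' Samples species records from a battery of templates that cover the
#' qualifying and masking cases of the land-use threat filter (category
#' gates, non-land-use threat codes, criteria based only on subletters
#' d/e), carrying the planted ground truth in the `qualifies` column.
#'
#' @param spec a [worldSpec()].
#' @param n number of records (default: 3 per template).
#' @return data.frame species, category, threat_codes, criteria, qualifies.
#' @export
genThreatRecords <- function(spec, n = 3L * nrow(.THREAT_TEMPLATES)) {
  set.seed(spec$seed + 303L)
  pick <- c(seq_len(nrow(.THREAT_TEMPLATES)),  # every case at least once
            sample(nrow(.THREAT_TEMPLATES), max(0, n - nrow(.THREAT_TEMPLATES)),
                   replace = TRUE))
  pick <- pick[seq_len(n)]
  out <- .THREAT_TEMPLATES[pick, , drop = FALSE]
  out <- cbind(species = sprintf("sp%03d", seq_len(n)), out)
  rownames(out) <- NULL
  out
}

# Voronoi country overlay: each ecoregion is split into 4 x 4 tiles around
# its centre; tiles join the nearest country seed, making the
# ecoregion-country overlap areas nontrivial.
.countryOverlay <- function(spec, ecoregions) {
  set.seed(spec$seed + 404L)
  seeds <- data.frame(country = paste0("country", seq_len(spec$nCountries)),
                      x = runif(spec$nCountries, 0, 10 *
                                  ceiling(sqrt(spec$nEcoregions))),
                      y = runif(spec$nCountries, 0, 10 *
                                  ceiling(sqrt(spec$nEcoregions))),
                      stringsAsFactors = FALSE)
  off <- seq(-3.75, 3.75, by = 2.5)
  tiles <- expand.grid(dx = off, dy = off)
  rows <- list()
  for (i in seq_len(nrow(ecoregions))) {
    tx <- ecoregions$x[i] + tiles$dx
    ty <- ecoregions$y[i] + tiles$dy
    d <- outer(tx, seeds$x, "-")^2 + outer(ty, seeds$y, "-")^2
    nearest <- max.col(-d, ties.method = "first")
    cnt <- table(factor(nearest, levels = seq_len(spec$nCountries)))
    for (k in which(cnt > 0)) {
      rows[[length(rows) + 1]] <- data.frame(
        ecoregion = ecoregions$ecoregion[i], country = seeds$country[k],
        area = ecoregions$area[i] * as.integer(cnt[k]) / nrow(tiles),
        stringsAsFactors = FALSE)
    }
  }
  list(countries = seeds, overlaps = do.call(rbind, rows))
}

#' Generate a complete synthetic world
#'
#' Assembles landscapes, parameter tables, GEPs, the biome assignment and
#' the Voronoi country overlay into a validated [SyntheticWorld-class].
#' Identical specs (same seed) yield byte-identical worlds.
#'
#' @param spec a [worldSpec()].
#' @return A [SyntheticWorld-class].
#' @examples
#' w <- genWorld(worldSpec(nEcoregions = 2, dim = c(15, 15), seed = 7))
#' w
#' @export
genWorld <- function(spec) {
  legend <- worldLegend(spec)
  nCells <- spec$dim[1] * spec$dim[2]
  side <- ceiling(sqrt(spec$nEcoregions))
  ecoregions <- data.frame(
    ecoregion = .ecoIds(spec), biome = .biomeOf(spec),
    area = nCells * spec$cellSize^2,
    x = 10 * (((seq_len(spec$nEcoregions) - 1) %% side) + 0.5),
    y = 10 * (((seq_len(spec$nEcoregions) - 1) %/% side) + 0.5),
    stringsAsFactors = FALSE)
  overlay <- .countryOverlay(spec, ecoregions)
  landscapes <- lapply(seq_len(spec$nEcoregions), function(i) {
    genLandscape(spec, i)
  })
  names(landscapes) <- .ecoIds(spec)
  new("SyntheticWorld", spec = unclass(spec), legend = legend,
      ecoregions = ecoregions, countries = overlay$countries,
      overlaps = overlay$overlaps, landscapes = landscapes,
      params = genParams(spec))
}
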