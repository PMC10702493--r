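#' @import methods
#' @importFrom stats median qnorm runif rnorm setNames weighted.mean cor pt
#'   pnorm sd
#' @importFrom utils read.csv write.csv
NULL

# Intensity levels in increasing management order; "natural" and "all" are
# special levels (reference state / pooled classes).
.INTENSITY_LEVELS <- c("minimal", "light", "intense")
.NATURAL <- "natural"

#' Categorical landscape raster
#'
#' A rectangular grid of integer land-cover codes for a single ecoregion,
#' with square cells of known edge length. Codes are interpreted through a
#' legend (see [makeLegend()]) mapping each code to a (land use, intensity)
#' class or to natural habitat. Areas are always in square metres.
#'
#' @slot codes integer matrix, one land-cover code per cell; row 1 is the
#'   top of the map.
#' @slot cellSize numeric(1), metres per cell edge (> 0).
#' @slot ecoregionId character(1) identifier.
#' @slot nodataCode integer(1) code marking cells outside the ecoregion.
#' @export
setClass("LandscapeGrid",
  representation(
    codes = "matrix",
    cellSize = "numeric",
    ecoregionId = "character",
    nodataCode = "integer"
  )
)

setValidity("LandscapeGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@codes)) {
    msg <- c(msg, "codes must be an integer matrix")
  }
  if (length(object@cellSize) != 1L || is.na(object@cellSize) ||
      object@cellSize <= 0) {
    msg <- c(msg, "cellSize must be a single positive number")
  }
  if (length(object@ecoregionId) != 1L) {
    msg <- c(msg, "ecoregionId must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LandscapeGrid
#'
#' @param codes integer matrix of land-cover codes (row 1 = top).
#' @param cellSize cell edge length in metres.
#' @param ecoregionId ecoregion identifier.
#' @param nodataCode code marking no-data cells (default -9999).
#' @return A [LandscapeGrid-class] object.
#' @examples
#' g <- landscapeGrid(matrix(0L, 4, 4), cellSize = 1000, ecoregionId = "eco1")
#' dim(codes(g))
#' @export
landscapeGrid <- function(codes, cellSize, ecoregionId = "eco",
                          nodataCode = -9999L) {
  storage.mode(codes) <- "integer"
  new("LandscapeGrid", codes = codes, cellSize = as.numeric(cellSize),
      ecoregionId = as.character(ecoregionId),
      nodataCode = as.integer(nodataCode))
}

#' Biological and spatial parameter tables
#'
#' Bundles the parameter tables driving the characterization-factor model:
#' relative local species richness (rr) with uncertainty per
#' (group, land use, intensity); species-area slopes z per (group, biome);
#' median dispersal distances per (group, ecoregion); habitat-suitability
#' species counts and pairwise overlap counts for vertebrates; regeneration
#' times; global extinction probabilities (GEPs); and the species-group
#' roster with kingdom membership.
#'
#' @slot rr data.frame: group, land_use, intensity, rr, se, lo, hi.
#' @slot z data.frame: group, biome, z (0 < z < 1).
#' @slot dispersal data.frame: group, ecoregion, d_med (metres).
#' @slot suitability data.frame: group, ecoregion, land_use, S, S_total.
#' @slot shared data.frame: group, ecoregion, habitat_land_use,
#'   surrounding_land_use, S_shared.
#' @slot regeneration data.frame: group, biome, land_use, t_reg (years).
#' @slot geps data.frame: group, ecoregion, gep; sums to 1 per group.
#' @slot groups data.frame: group, kingdom ("plant" or "animal").
#' @export
setClass("ParamSet",
  representation(
    rr = "data.frame",
    z = "data.frame",
    dispersal = "data.frame",
    suitability = "data.frame",
    shared = "data.frame",
    regeneration = "data.frame",
    geps = "data.frame",
    groups = "data.frame"
  )
)

setValidity("ParamSet", function(object) {
  msg <- character()
  rr <- object@rr
  need <- c("group", "land_use", "intensity", "rr", "se", "lo", "hi")
  if (!all(need %in% names(rr))) {
    msg <- c(msg, paste("rr table needs columns:", paste(need, collapse = ", ")))
  } else {
    if (any(rr$rr <= 0)) msg <- c(msg, "rr must be > 0")
    if (any(rr$lo > rr$rr | rr$rr > rr$hi)) {
      msg <- c(msg, "rr bounds must satisfy lo <= rr <= hi")
    }
  }
  if (nrow(object@z) && (any(object@z$z <= 0) || any(object@z$z >= 1))) {
    msg <- c(msg, "z values must lie in (0, 1)")
  }
  if (nrow(object@dispersal) && any(object@dispersal$d_med <= 0)) {
    msg <- c(msg, "dispersal distances must be positive")
  }
  if (nrow(object@geps)) {
    if (any(object@geps$gep < 0 | object@geps$gep > 1)) {
      msg <- c(msg, "GEPs must lie in [0, 1]")
    }
    sums <- tapply(object@geps$gep, object@geps$group, sum)
    if (any(abs(sums - 1) > 1e-9)) {
      msg <- c(msg, "GEPs must sum to 1 per species group")
    }
  }
  if (nrow(object@regeneration) && any(object@regeneration$t_reg <= 0)) {
    msg <- c(msg, "regeneration times must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ParamSet
#'
#' @param rr,z,dispersal,suitability,shared,regeneration,geps,groups see
#'   [ParamSet-class] slot documentation.
#' @return A validated [ParamSet-class] object.
#' @export
paramSet <- function(rr, z, dispersal,
                     suitability = data.frame(),
                     shared = data.frame(),
                     regeneration = data.frame(),
                     geps = data.frame(),
                     groups = data.frame()) {
  new("ParamSet", rr = rr, z = z, dispersal = dispersal,
      suitability = suitability, shared = shared,
      regeneration = regeneration, geps = geps, groups = groups)
}

#' A complete synthetic study system
#'
#' Holds the ecoregion mosaic (with biome membership and a country overlay),
#' one categorical landscape per ecoregion, and an internally consistent
#' [ParamSet-class] with known ground truth, so that the full
#' characterization-factor pipeline can run without any external data.
#'
#' @slot spec list, the generating [worldSpec()].
#' @slot legend data.frame: code, land_use, intensity.
#' @slot ecoregions data.frame: ecoregion, biome, area (m^2), x, y.
#' @slot countries data.frame: country, x, y (centroids).
#' @slot overlaps data.frame: ecoregion, country, area (m^2).
#' @slot landscapes named list of [LandscapeGrid-class], one per ecoregion.
#' @slot params a [ParamSet-class].
#' @export
setClass("SyntheticWorld",
  representation(
    spec = "list",
    legend = "data.frame",
    ecoregions = "data.frame",
    countries = "data.frame",
    overlaps = "data.frame",
    landscapes = "list",
    params = "ParamSet"
  )
)

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  eco <- object@ecoregions
  if (!all(c("ecoregion", "biome", "area") %in% names(eco))) {
    msg <- c(msg, "ecoregions needs columns ecoregion, biome, area")
  }
  if (!all(eco$ecoregion %in% names(object@landscapes))) {
    msg <- c(msg, "every ecoregion needs a landscape")
  }
  ov <- object@overlaps
  if (nrow(ov)) {
    if (any(ov$area < 0)) msg <- c(msg, "overlap areas must be >= 0")
    tot <- tapply(ov$area, ov$ecoregion, sum)
    full <- eco$area[match(names(tot), eco$ecoregion)]
    if (any(tot > full * (1 + 1e-9))) {
      msg <- c(msg, "country overlaps of an ecoregion must not exceed its area")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LandscapeGrid", function(object) {
  d <- dim(object@codes)
  n <- sum(object@codes != object@nodataCode)
  cat("LandscapeGrid '", object@ecoregionId, "': ", d[1], " x ", d[2],
      " cells of ", object@cellSize, " m (", n, " in ecoregion, ",
      length(unique(object@codes[object@codes != object@nodataCode])),
      " classes)\n", sep = "")
})

setMethod("show", "ParamSet", function(object) {
  cat("ParamSet:", length(unique(object@rr$group)), "groups,",
      length(unique(object@rr$land_use)), "land uses,",
      length(unique(object@z$biome)), "biomes,",
      length(unique(object@dispersal$ecoregion)), "ecoregions\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", nrow(object@ecoregions), "ecoregions in",
      length(unique(object@ecoregions$biome)), "biomes,",
      nrow(object@countries), "countries, seed",
      object@spec$seed, "\n")
})
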