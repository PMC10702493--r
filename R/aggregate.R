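#' Aggregate characterization factors across taxa
#'
#' Two-step equal-weight aggregation: vertebrate groups are averaged first
#' (each group counting equally regardless of its species number), then the
#' plant CF and the vertebrate mean are averaged:
#' `CF_agg = 0.5 * (CF_plants + mean(CF_vertebrates))`.
#'
#' @param cfByGroup named numeric vector of CFs per species group.
#' @param plantGroup name of the plant group (default "plants").
#' @return A list with `value` (aggregated CF), `vertebrate_mean`,
#'   and `flagged` (`TRUE` when a kingdom is missing and only the available
#'   kingdom's mean is returned).
#' @examples
#' aggregateTaxa(c(plants = 0.2, birds = 0.1, mammals = 0.2,
#'                 amphibians = 0.3, reptiles = 0.4))
#' @export
aggregateTaxa <- function(cfByGroup, plantGroup = "plants") {
  stopifnot(length(cfByGroup) >= 1, !is.null(names(cfByGroup)))
  plants <- cfByGroup[names(cfByGroup) == plantGroup]
  verts <- cfByGroup[names(cfByGroup) != plantGroup]
  vMean <- if (length(verts)) mean(verts) else NA_real_
  if (!length(plants) || !length(verts)) {
    warning("missing kingdom: returning kingdom-level aggregate only")
    value <- if (length(plants)) unname(plants[1]) else vMean
    return(list(value = value, vertebrate_mean = vMean, flagged = TRUE))
  }
  list(value = 0.5 * (unname(plants[1]) + vMean), vertebrate_mean = vMean,
       flagged = FALSE)
}

#' Area-weighted spatial aggregation with uncertainty
#'
#' Aggregates ecoregion-level CFs to a country or the globe as the weighted
#' mean with ecoregion (or land-use) areas as weights, and reports the
#' relative weighted standard deviation as the spatial-uncertainty measure.
#'
#' @param cf numeric vector of ecoregion CFs.
#' @param weights non-negative weights (at least one positive).
#' @return list with `value` (weighted mean), `sd` (weighted SD) and
#'   `rel_sd` (weighted SD / weighted mean; NA for a zero mean).
#' @examples
#' aggregateSpatial(c(1e-12, 3e-12), c(1, 3))
#' @export
aggregateSpatial <- function(cf, weights) {
  stopifnot(length(cf) == length(weights))
  if (any(weights < 0)) stop("weights must be >= 0")
  if (sum(weights) == 0) stop("all weights are zero")
  m <- sum(weights * cf) / sum(weights)
  v <- sum(weights * (cf - m)^2) / sum(weights)
  s <- sqrt(v)
  list(value = m, sd = s, rel_sd = if (m != 0) s / m else NA_real_)
}

.intensityRank <- function(x) match(x, .INTENSITY_LEVELS)

#' Intensity-sibling proxy for a missing CF
#'
#' When a land use exists in the ecoregion at another intensity level, the
#' missing level's CF is rescaled from the nearest available sibling via the
#' affinity pathway: within an ecoregion the average occupation CF of a
#' class is proportional to its habitat deficit `(1 - h)`, so
#' `CF_target = CF_source * (1 - h_target) / (1 - h_source)`.
#'
#' @param siblings data.frame with columns intensity, value, h for the
#'   available levels of the land use.
#' @param targetIntensity the missing level.
#' @param hTarget affinity of the missing level.
#' @return list with `value` and `source` (the donor intensity), or `NULL`
#'   when no usable sibling exists (fall through to [proxyBiome()]).
#' @export
proxyIntensity <- function(siblings, targetIntensity, hTarget) {
  usable <- siblings[!is.na(siblings$value) & siblings$h < 1, , drop = FALSE]
  if (!nrow(usable)) return(NULL)
  if (targetIntensity %in% usable$intensity) {
    i <- which(usable$intensity == targetIntensity)[1]
    return(list(value = usable$value[i], source = targetIntensity))
  }
  gap <- abs(.intensityRank(usable$intensity) -
             .intensityRank(targetIntensity))
  # nearest available level; ties broken toward the lower intensity
  i <- order(gap, .intensityRank(usable$intensity))[1]
  ratio <- (1 - hTarget) / (1 - usable$h[i])
  list(value = usable$value[i] * ratio, source = usable$intensity[i])
}

#' Biome-average proxy for a missing CF
#'
#' Averages the natively computed regional CFs of the same class from donor
#' ecoregions within the same biome; for a global CF the average is then
#' multiplied by the GEP of the ecoregion of interest. Proxy-derived donors
#' are excluded to avoid cascades.
#'
#' @param donorCfs regional CF values of donor ecoregions (native only).
#' @param gep GEP of the target ecoregion; `NA` for a regional proxy.
#' @return Proxy CF value, or `NA` when the donor pool is empty.
#' @export
proxyBiome <- function(donorCfs, gep = NA) {
  donorCfs <- donorCfs[!is.na(donorCfs)]
  if (!length(donorCfs)) return(NA_real_)
  m <- mean(donorCfs)
  if (is.na(gep)) m else m * gep
}

#' Biome-density proxy for a missing GEP
#'
#' Divides the GEPs of donor ecoregions in the same biome by their areas,
#' averages the densities, and multiplies by the area of the ecoregion of
#' interest.
#'
#' @param donorGeps GEPs of donor ecoregions.
#' @param donorAreas areas (m^2) of the same donors.
#' @param areaTarget area (m^2) of the target ecoregion.
#' @return Proxy GEP.
#' @export
proxyGEP <- function(donorGeps, donorAreas, areaTarget) {
  ok <- !is.na(donorGeps) & !is.na(donorAreas) & donorAreas > 0
  if (!any(ok)) return(NA_real_)
  mean(donorGeps[ok] / donorAreas[ok]) * areaTarget
}

#' Nearest-neighbour country proxy
#'
#' For a country that cannot be matched with ecoregions: the simple average
#' of the three nearest countries' CFs (centroid distance, ties broken by
#' identifier order), with the spatial-uncertainty SDs pooled as
#' `sqrt(mean(sd^2) + var_between(means))`.
#'
#' @param target two-element numeric (x, y) centroid of the target country.
#' @param candidates data.frame with columns country, x, y, value, sd.
#' @param k number of neighbours (default 3; fewer are used, with a
#'   warning, when fewer candidates exist).
#' @return list with `value`, `sd` (pooled) and `neighbours`.
#' @export
proxyCountry <- function(target, candidates, k = 3) {
  if (!nrow(candidates)) stop("no candidate countries")
  if (nrow(candidates) < k) {
    warning("fewer than ", k, " candidate countries: using all available")
    k <- nrow(candidates)
  }
  d <- sqrt((candidates$x - target[1])^2 + (candidates$y - target[2])^2)
  o <- order(d, candidates$country)
  sel <- candidates[o[seq_len(k)], , drop = FALSE]
  m <- mean(sel$value)
  pooled <- sqrt(mean(sel$sd^2) + mean((sel$value - m)^2))
  list(value = m, sd = pooled, neighbours = sel$country)
}
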