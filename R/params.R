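#' Habitat affinity from relative species richness
#'
#' Converts the relative local species richness of a land-use class into a
#' habitat affinity on the suitability scale of the species-area slope:
#' `h = min(1, rr^(1/z))`. Affinity is capped at 1 because sampled local
#' richness can exceed the natural reference.
#'
#' @param rr relative local species richness (> 0, natural reference = 1).
#' @param z species-area slope in (0, 1).
#' @return Affinity in (0, 1\].
#' @examples
#' affinityFromRR(0.5, 0.25)  # 0.0625
#' @export
affinityFromRR <- function(rr, z) {
  if (any(rr <= 0)) stop("rr must be positive")
  if (any(z <= 0 | z >= 1)) stop("z must lie in (0, 1)")
  pmin(1, rr^(1 / z))
}

#' Back-calculate relative richness from an affinity
#'
#' Inverse of [affinityFromRR()]: `rr = h^z`. Used when one class of a
#' resistance pair carries an ecoregion-specific affinity rather than a
#' richness estimate.
#'
#' @param h affinity in (0, 1\].
#' @param z species-area slope in (0, 1).
#' @return Equivalent relative richness.
#' @export
rrFromAffinity <- function(h, z) {
  if (any(h <= 0 | h > 1)) stop("h must lie in (0, 1]")
  if (any(z <= 0 | z >= 1)) stop("z must lie in (0, 1)")
  h^z
}

#' Intensity scaling factor
#'
#' Globally defined scaling factor of a land use type: the ratio of relative
#' species richness at intensity m to the richness at minimal intensity.
#' Values above 1 are possible empirically and are flagged with a warning.
#'
#' @param rr_m richness at the target intensity (> 0).
#' @param rr_minimal richness at minimal intensity (> 0).
#' @return f, dimensionless; f(minimal) = 1.
#' @export
intensityScalingFactor <- function(rr_m, rr_minimal) {
  if (any(rr_m <= 0) || any(rr_minimal <= 0)) {
    stop("richness values must be positive")
  }
  f <- rr_m / rr_minimal
  if (any(f > 1)) {
    warning("scaling factor > 1: intensity richness exceeds minimal-use richness")
  }
  f
}

#' Rescale a broad-class affinity for land-use intensity
#'
#' Applies an intensity scaling factor to an ecoregion-level broad-class
#' affinity in richness space, i.e. through the 1/z exponent, so that broad
#' and intensity information combine on the affinity scale consistently
#' with [affinityFromRR()]: `h_im = min(1, h_broad * f^(1/z))`.
#'
#' @param h_broad ecoregion-level affinity of the broad land-use class.
#' @param f scaling factor from [intensityScalingFactor()].
#' @param z species-area slope in (0, 1).
#' @return Rescaled affinity in \[0, 1\].
#' @export
rescaleAffinity <- function(h_broad, f, z) {
  if (any(h_broad < 0 | h_broad > 1)) stop("h_broad must lie in [0, 1]")
  if (any(f <= 0)) stop("f must be positive")
  pmin(1, h_broad * f^(1 / z))
}

# Welch's t-test on two model estimates with standard errors. With no sample
# sizes attached to model estimates the default reference is normal
# (df = Inf); Welch-Satterthwaite df are used when per-estimate df are given.
.welchP <- function(est1, se1, est2, se2, df1 = Inf, df2 = Inf) {
  if (is.na(se1) || is.na(se2)) return(NA_real_)
  t <- (est1 - est2) / sqrt(se1^2 + se2^2)
  if (is.finite(df1) && is.finite(df2)) {
    df <- (se1^2 + se2^2)^2 / (se1^4 / df1 + se2^4 / df2)
    2 * pt(-abs(t), df)
  } else {
    2 * pnorm(-abs(t))
  }
}

#' Merge practically and statistically indistinguishable intensity levels
#'
#' Adjacent intensity levels of one land use are merged when the absolute
#' difference of their richness estimates is below `absThreshold` (practical
#' insignificance) and Welch's t-test on the estimates and standard errors
#' is non-significant at `alpha`. Merging is evaluated pairwise in intensity
#' order and closed transitively; merged estimates are inverse-variance
#' weighted means.
#'
#' @param estimates data.frame with columns intensity, rr, se (one row per
#'   level, any subset of minimal/light/intense), optional column df.
#' @param absThreshold practical-insignificance threshold on \|delta rr\|.
#' @param alpha significance level for Welch's t-test.
#' @return data.frame with columns intensity (merged labels such as
#'   "minimal+light"), members (comma-separated originals), rr, se.
#' @examples
#' mergeIntensityLevels(data.frame(intensity = c("minimal", "light"),
#'                                 rr = c(0.62, 0.60), se = c(0.05, 0.05)))
#' @export
mergeIntensityLevels <- function(estimates, absThreshold = 0.05,
                                 alpha = 0.05) {
  if (nrow(estimates) < 2) stop("need at least two intensity levels")
  ord <- match(estimates$intensity, .INTENSITY_LEVELS)
  if (any(is.na(ord))) stop("unknown intensity labels")
  estimates <- estimates[order(ord), , drop = FALSE]
  n <- nrow(estimates)
  if (is.null(estimates$df)) estimates$df <- Inf
  if (any(is.na(estimates$se))) {
    warning("missing standard error: levels kept separate where untestable")
  }
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    p <- .welchP(estimates$rr[i], estimates$se[i],
                 estimates$rr[i + 1], estimates$se[i + 1],
                 estimates$df[i], estimates$df[i + 1])
    mergeable <- !is.na(p) &&
      abs(estimates$rr[i] - estimates$rr[i + 1]) < absThreshold &&
      p >= alpha
    if (mergeable) grp[grp == grp[i + 1]] <- grp[i]  # transitive closure
  }
  out <- lapply(unique(grp), function(gkey) {
    sel <- grp == gkey
    w <- 1 / estimates$se[sel]^2
    if (any(!is.finite(w))) w <- rep(1, sum(sel))
    data.frame(
      intensity = paste(estimates$intensity[sel], collapse = "+"),
      members = paste(estimates$intensity[sel], collapse = ","),
      rr = sum(w * estimates$rr[sel]) / sum(w),
      se = sqrt(1 / sum(1 / estimates$se[sel]^2)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Landscape resistance for plants
#'
#' Species overlap between plant habitat and matrix is unobserved, so
#' resistance is estimated from relative richness: a surrounding class that
#' supports at least the habitat's richness is fully permeable (r = 0);
#' otherwise `r = 1 - min(1, rr_surrounding / rr_habitat)`.
#'
#' @param rr_habitat richness of the habitat class (> 0).
#' @param rr_surrounding richness of the surrounding class (> 0).
#' @return Resistance in \[0, 1\].
#' @export
resistancePlants <- function(rr_habitat, rr_surrounding) {
  if (any(rr_habitat <= 0) || any(rr_surrounding <= 0)) {
    stop("richness values must be positive")
  }
  1 - pmin(1, rr_surrounding / rr_habitat)
}

#' Landscape resistance for vertebrates
#'
#' Resistance from the shared-species fraction between the habitat and the
#' surrounding class, degraded by the surrounding class's intensity scaling
#' factor: `r = 1 - (S_shared / S_habitat) * min(1, f_surrounding)`.
#'
#' @param S_habitat species count of the habitat class (> 0).
#' @param S_shared species shared with the surrounding class
#'   (0 <= S_shared <= S_habitat).
#' @param f_surrounding intensity scaling factor of the surrounding class.
#' @return Resistance in \[0, 1\].
#' @export
resistanceVertebrates <- function(S_habitat, S_shared, f_surrounding) {
  if (any(S_habitat <= 0)) stop("S_habitat must be positive")
  if (any(S_shared < 0 | S_shared > S_habitat)) {
    stop("S_shared must lie in [0, S_habitat]")
  }
  if (any(f_surrounding <= 0)) stop("f must be positive")
  1 - (S_shared / S_habitat) * pmin(1, f_surrounding)
}

#' Fill missing dispersal distances from taxonomy
#'
#' Replaces missing per-species maximum dispersal distances by the average
#' over the nearest taxonomic level with data: genus, then family, order,
#' class and, as a last resort, kingdom. Observed values are never altered
#' and the fill level is recorded.
#'
#' @param traits data.frame with columns species, genus, family, order,
#'   class, kingdom, dispersal_m (NA where unknown).
#' @return The table with dispersal_m completed and a fill_level column
#'   ("observed", "genus", ..., "kingdom").
#' @export
fillDispersalGaps <- function(traits) {
  if (!nrow(traits)) stop("empty trait table")
  if (all(is.na(traits$dispersal_m))) {
    stop("no species with a known dispersal distance")
  }
  if (any(traits$dispersal_m <= 0, na.rm = TRUE)) {
    stop("dispersal distances must be positive")
  }
  known <- !is.na(traits$dispersal_m)
  traits$fill_level <- ifelse(known, "observed", NA_character_)
  for (level in c("genus", "family", "order", "class", "kingdom")) {
    todo <- is.na(traits$dispersal_m)
    if (!any(todo)) break
    means <- tapply(traits$dispersal_m[known], traits[[level]][known], mean)
    fill <- means[traits[[level]][todo]]
    ok <- !is.na(fill)
    traits$dispersal_m[todo][ok] <- as.numeric(fill[ok])
    traits$fill_level[todo][ok] <- level
  }
  if (any(is.na(traits$dispersal_m))) {
    stop("taxonomy incomplete: some species could not be gap-filled")
  }
  traits
}

#' Median dispersal distance per species group and ecoregion
#'
#' The median of the (gap-filled) species dispersal distances over the
#' species of a group present in each ecoregion. For amphibians and
#' reptiles the configured constant (default 9 km) applies everywhere.
#'
#' @param traits gap-filled trait table with columns species, group,
#'   dispersal_m (run [fillDispersalGaps()] first).
#' @param presence data.frame with columns species, ecoregion.
#' @param constantGroups species groups that receive `constantDistance`.
#' @param constantDistance dispersal distance (m) for `constantGroups`.
#' @return data.frame: group, ecoregion, d_med (NA, flagged via the
#'   `missing` column, where a group has no species present).
#' @export
medianDispersal <- function(traits, presence,
                            constantGroups = c("amphibians", "reptiles"),
                            constantDistance = 9000) {
  if (any(is.na(traits$dispersal_m))) {
    stop("trait table has gaps: run fillDispersalGaps() first")
  }
  ecoregions <- unique(presence$ecoregion)
  groups <- unique(traits$group)
  out <- expand.grid(group = groups, ecoregion = ecoregions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$d_med <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$group[i] %in% constantGroups) {
      out$d_med[i] <- constantDistance
      next
    }
    sp <- presence$species[presence$ecoregion == out$ecoregion[i]]
    d <- traits$dispersal_m[traits$group == out$group[i] &
                            traits$species %in% sp]
    if (length(d)) out$d_med[i] <- median(d)
  }
  out$missing <- is.na(out$d_med)
  if (any(out$missing)) {
    warning(sum(out$missing),
            " (group, ecoregion) pairs lack species: flagged for proxies")
  }
  out
}
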