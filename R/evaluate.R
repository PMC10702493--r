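#' Spearman rank correlation
#'
#' Nonparametric correlation on ranks (average ranks for ties), as used for
#' comparing CF sets and sensitivity variants.
#'
#' @param a,b numeric vectors of equal length (>= 3), neither constant.
#' @return rho in \[-1, 1\].
#' @export
spearmanRho <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("Spearman correlation undefined for a constant vector")
  }
  cor(a, b, method = "spearman")
}

#' Percent bias
#'
#' Sum-based percent bias with the newer values as the reference:
#' `100 * sum(old - new) / sum(new)`, so a negative value means the older
#' set is smaller.
#'
#' @param old the older (compared) values.
#' @param new the newer (reference) values; their sum must be nonzero.
#' @return Percent bias.
#' @examples
#' percentBias(c(0.9, 1.8), c(1, 2))  # -10
#' @export
percentBias <- function(old, new) {
  if (length(old) != length(new)) stop("vectors must have equal length")
  if (sum(new) == 0) stop("reference sum is zero")
  100 * sum(old - new) / sum(new)
}

#' Contribution to variance from rank correlations
#'
#' The share of each explanatory factor is its squared Spearman correlation
#' with the CFs, normalized by the sum of squared correlations over all
#' factors. Typical factors: habitat affinity, ecoregion area, used-area
#' share, ECA relative to used area, z-value and GEP.
#'
#' @param factors named list (or data.frame) of factor value vectors.
#' @param cf CF (or RSL) values, same length as each factor.
#' @return Named shares summing to 1.
#' @export
contributionToVariance <- function(factors, cf) {
  factors <- as.list(factors)
  if (length(factors) < 2) stop("need at least two factors")
  rho <- vapply(factors, function(f) spearmanRho(f, cf), 0)
  total <- sum(rho^2)
  if (total == 0) stop("all correlations are zero: shares undefined")
  rho^2 / total
}

#' Engine options for a named sensitivity variant
#'
#' `default` is the full model; `rr_lo` / `rr_hi` use the 2.5% / 97.5%
#' bounds of relative species richness; `no_intensity` pools intensity
#' levels; `no_fragmentation` replaces ECAs by total class areas.
#'
#' @param name one of "default", "rr_lo", "rr_hi", "no_intensity",
#'   "no_fragmentation".
#' @return Options list for [cfOptions()] consumers.
#' @export
variantOptions <- function(name = c("default", "rr_lo", "rr_hi",
                                    "no_intensity", "no_fragmentation")) {
  name <- match.arg(name)
  switch(name,
    default = cfOptions(),
    rr_lo = cfOptions(rrBound = "lo"),
    rr_hi = cfOptions(rrBound = "hi"),
    no_intensity = cfOptions(intensity = FALSE),
    no_fragmentation = cfOptions(fragmentation = FALSE))
}

#' Regional species loss per ecoregion for one variant
#'
#' @param world a [SyntheticWorld-class].
#' @param variant variant name (see [variantOptions()]).
#' @param groups species groups (default all).
#' @return data.frame: ecoregion, group, variant, rsl.
#' @export
ecoregionRSL <- function(world, variant = "default", groups = NULL) {
  options <- variantOptions(variant)
  params <- worldParams(world)
  if (is.null(groups)) groups <- params@groups$group
  eco <- ecoregionTable(world)
  rows <- list()
  for (i in seq_len(nrow(eco))) {
    for (g in groups) {
      state <- habitatState(landscapes(world)[[eco$ecoregion[i]]],
                            classLegend(world), params, g,
                            eco$ecoregion[i], eco$biome[i], options)
      rows[[length(rows) + 1]] <- data.frame(
        ecoregion = eco$ecoregion[i], group = g, variant = variant,
        rsl = regionalSpeciesLoss(state$H1, state$H0, state$z),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the sensitivity variants and compare them to the default
#'
#' Computes the ecoregion-level regional species loss under the default
#' model and each requested variant, then compares each variant against the
#' default by Spearman correlation and percent bias (default as the
#' reference), on RSL rather than CFs since the land-use area is identical
#' across variants.
#'
#' @param world a [SyntheticWorld-class].
#' @param variants variant names to run (besides the default).
#' @param groups species groups (default all).
#' @return list with `rsl` (long table of ecoregion x group x variant) and
#'   `comparison` (variant, spearman, percent_bias).
#' @export
runVariants <- function(world,
                        variants = c("rr_lo", "rr_hi", "no_intensity",
                                     "no_fragmentation"),
                        groups = NULL) {
  all <- lapply(c("default", variants), function(v) {
    ecoregionRSL(world, v, groups)
  })
  rsl <- do.call(rbind, all)
  base <- all[[1]]
  comparison <- do.call(rbind, lapply(seq_along(variants), function(i) {
    v <- all[[i + 1]]
    stopifnot(identical(v$ecoregion, base$ecoregion),
              identical(v$group, base$group))
    rho <- if (length(base$rsl) >= 3 && sd(base$rsl) > 0 && sd(v$rsl) > 0) {
      spearmanRho(v$rsl, base$rsl)
    } else {
      NA_real_
    }
    data.frame(variant = variants[i], spearman = rho,
               percent_bias = percentBias(v$rsl, base$rsl),
               stringsAsFactors = FALSE)
  }))
  list(rsl = rsl, comparison = comparison)
}

# Land-use threat codes: residential/commercial development (1) and
# agriculture subcodes 2.1 (crops), 2.2 (plantations), 2.3 (livestock),
# including their sub-levels.
.LU_THREAT_PREFIXES <- c("1", "2.1", "2.2", "2.3")

.isLandUseThreat <- function(code) {
  code <- trimws(code)
  vapply(code, function(x) {
    any(x == .LU_THREAT_PREFIXES |
        startsWith(x, paste0(.LU_THREAT_PREFIXES, ".")))
  }, TRUE, USE.NAMES = FALSE)
}

# Parse an IUCN criteria string like "A2cd; B1ab(iii)" into entries.
.parseCriteria <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character())
  parts <- unlist(strsplit(s, "[;+]"))
  trimws(parts[nzchar(trimws(parts))])
}

# TRUE when the category rests only on A1-A4 criteria whose subletters are
# all d and/or e (exploitation, introduced taxa, pollutants, ...).
.onlyDECriteria <- function(entries) {
  if (!length(entries)) return(FALSE)
  isA <- grepl("^A[1-4]", entries)
  if (!all(isA)) return(FALSE)
  sub <- gsub("^A[1-4]", "", entries)
  sub <- gsub("\\(.*?\\)", "", sub)
  subletters <- unlist(strsplit(sub, ""))
  subletters <- subletters[subletters %in% c("a", "b", "c", "d", "e")]
  length(subletters) > 0 && all(subletters %in% c("d", "e"))
}

#' Filter species threatened specifically by land use
#'
#' Keeps species whose Red List category is threatened (VU, EN, CR, EW or
#' EX), that face at least one land-use threat (codes 1, 2.1, 2.2 or 2.3,
#' including sub-levels), and whose threat criteria are not A1-A4 based on
#' only the subletters d and/or e.
#'
#' @param records data.frame with columns species, category, threat_codes
#'   (codes separated by ";" or "|"), criteria (IUCN criteria string).
#' @return Character vector of qualifying species ids.
#' @export
filterThreatened <- function(records) {
  categories <- c("LC", "NT", "VU", "EN", "CR", "EW", "EX", "DD")
  bad <- !(records$category %in% categories)
  if (any(bad)) {
    warning("skipping records with malformed categories: ",
            paste(records$species[bad], collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  threatened <- records$category %in% c("VU", "EN", "CR", "EW", "EX")
  keep <- logical(nrow(records))
  for (i in which(threatened)) {
    codes <- unlist(strsplit(records$threat_codes[i], "[;|]"))
    codes <- trimws(codes[nzchar(trimws(codes))])
    if (!length(codes) || !any(.isLandUseThreat(codes))) next
    entries <- .parseCriteria(records$criteria[i])
    if (.onlyDECriteria(entries)) next
    keep[i] <- TRUE
  }
  records$species[keep]
}
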