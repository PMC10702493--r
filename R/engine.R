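#' Options for the characterization-factor engine
#'
#' @param fragmentation consider habitat fragmentation (ECA) or use total
#'   class areas (`FALSE` gives the no-fragmentation variant).
#' @param intensity distinguish land-use intensity levels; if `FALSE`,
#'   classes of one land use are pooled ("all") and richness estimates are
#'   combined by inverse-variance weighting.
#' @param rrBound which richness estimate drives affinities and
#'   resistances: the point estimate or the 2.5%/97.5% confidence bound.
#' @param fdStep relative step of the central finite difference behind
#'   marginal CFs.
#' @param cutoff pairwise dispersal probabilities below this are zeroed.
#' @param connectivity patch neighbourhood rule (4 or 8).
#' @return A named list of options.
#' @export
cfOptions <- function(fragmentation = TRUE, intensity = TRUE,
                      rrBound = c("point", "lo", "hi"), fdStep = 1e-4,
                      cutoff = 1e-6, connectivity = 8) {
  list(fragmentation = fragmentation, intensity = intensity,
       rrBound = match.arg(rrBound), fdStep = fdStep, cutoff = cutoff,
       connectivity = connectivity)
}

.rrCol <- function(bound) switch(bound, point = "rr", lo = "lo", hi = "hi")

.rrValue <- function(params, group, landUse, intensity, bound = "point") {
  rr <- params@rr
  i <- which(rr$group == group & rr$land_use == landUse &
             rr$intensity == intensity)
  if (!length(i)) return(NA_real_)
  rr[[.rrCol(bound)]][i[1]]
}

.zValue <- function(params, group, biome) {
  z <- params@z
  i <- which(z$group == group & z$biome == biome)
  if (!length(i)) return(NA_real_)
  z$z[i[1]]
}

.kingdom <- function(params, group) {
  g <- params@groups
  i <- which(g$group == group)
  if (!length(i)) stop("unknown species group: ", group)
  g$kingdom[i[1]]
}

.suitability <- function(params, group, ecoregion, landUse) {
  s <- params@suitability
  i <- which(s$group == group & s$ecoregion == ecoregion &
             s$land_use == landUse)
  if (!length(i)) return(c(S = NA_real_, S_total = NA_real_))
  c(S = s$S[i[1]], S_total = s$S_total[i[1]])
}

.sharedCount <- function(params, group, ecoregion, habitatLU, surroundingLU) {
  s <- params@shared
  i <- which(s$group == group & s$ecoregion == ecoregion &
             s$habitat_land_use == habitatLU &
             s$surrounding_land_use == surroundingLU)
  if (!length(i)) return(NA_real_)
  s$S_shared[i[1]]
}

# Intensity scaling factor with the confidence bound applied to the
# numerator only; the minimal-intensity denominator stays at the point
# estimate so that bounded variants move monotonically.
.scalingFactor <- function(params, group, landUse, intensity,
                           bound = "point") {
  num <- .rrValue(params, group, landUse, intensity, bound)
  den <- .rrValue(params, group, landUse, "minimal", "point")
  if (is.na(den)) {  # single-intensity land use: lowest level is baseline
    ints <- params@rr$intensity[params@rr$group == group &
                                params@rr$land_use == landUse]
    if (!length(ints)) return(NA_real_)
    base <- ints[which.min(match(ints, c(.INTENSITY_LEVELS, "all")))]
    den <- .rrValue(params, group, landUse, base, "point")
  }
  if (is.na(num) || is.na(den)) return(NA_real_)
  num / den
}

# Habitat affinity of one (land use, intensity) class for a species group in
# an ecoregion. Plants (and managed forests for vertebrates) go through the
# richness route; other vertebrate classes through ecoregion-level
# suitability counts rescaled for intensity.
.affinity <- function(params, group, ecoregion, biome, landUse, intensity,
                      bound = "point") {
  if (landUse == .NATURAL) return(1)
  z <- .zValue(params, group, biome)
  if (is.na(z)) return(NA_real_)
  kingdom <- .kingdom(params, group)
  if (kingdom == "plant" || landUse == "managed_forest") {
    rr <- .rrValue(params, group, landUse, intensity, bound)
    if (is.na(rr)) return(NA_real_)
    return(affinityFromRR(rr, z))
  }
  s <- .suitability(params, group, ecoregion, landUse)
  if (is.na(s["S"])) return(NA_real_)
  hBroad <- unname(s["S"] / s["S_total"])
  if (intensity == "all") return(min(1, hBroad))  # no intensity rescaling
  f <- .scalingFactor(params, group, landUse, intensity, bound)
  if (is.na(f)) return(NA_real_)
  rescaleAffinity(hBroad, f, z)
}

# Richness-equivalent of a class for resistance pairs involving
# ecoregion-specific affinities: rr = h^z.
.rrEquivalent <- function(params, group, ecoregion, biome, landUse,
                          intensity, bound = "point") {
  if (landUse == .NATURAL) return(1)
  kingdom <- .kingdom(params, group)
  if (kingdom == "plant" || landUse == "managed_forest") {
    return(.rrValue(params, group, landUse, intensity, bound))
  }
  h <- .affinity(params, group, ecoregion, biome, landUse, intensity, bound)
  z <- .zValue(params, group, biome)
  if (is.na(h) || is.na(z)) return(NA_real_)
  rrFromAffinity(max(h, 1e-12), z)
}

# Resistance of a surrounding class against movement between patches of a
# habitat class. Natural habitat and the habitat class itself are fully
# permeable. The confidence bound perturbs the surrounding class only; the
# habitat reference stays at the point estimate (see vignette).
.classResistance <- function(params, group, ecoregion, biome,
                             habitatLU, habitatInt,
                             surroundingLU, surroundingInt,
                             bound = "point") {
  if (surroundingLU == .NATURAL) return(0)
  if (surroundingLU == habitatLU && identical(surroundingInt, habitatInt)) {
    return(0)
  }
  kingdom <- .kingdom(params, group)
  plantRoute <- kingdom == "plant" || habitatLU == "managed_forest" ||
    surroundingLU == "managed_forest"
  if (plantRoute) {
    rrHab <- .rrEquivalent(params, group, ecoregion, biome, habitatLU,
                           habitatInt, "point")
    rrSur <- .rrEquivalent(params, group, ecoregion, biome, surroundingLU,
                           surroundingInt, bound)
    if (is.na(rrHab) || is.na(rrSur)) return(NA_real_)
    return(resistancePlants(rrHab, rrSur))
  }
  sHab <- if (habitatLU == .NATURAL) {
    .suitability(params, group, ecoregion, surroundingLU)["S_total"]
  } else {
    .suitability(params, group, ecoregion, habitatLU)["S"]
  }
  shared <- .sharedCount(params, group, ecoregion, habitatLU, surroundingLU)
  if (is.na(sHab) || is.na(shared)) return(NA_real_)
  f <- if (surroundingInt %in% c("all")) 1
       else .scalingFactor(params, group, surroundingLU, surroundingInt, bound)
  if (is.na(f)) return(NA_real_)
  resistanceVertebrates(unname(sHab), min(shared, unname(sHab)), f)
}

# Per-cell resistance map builder for a given species group; returns a
# function (landUse, intensity) -> matrix usable by classConnectivity().
.resistanceFunFor <- function(grid, legend, params, group, ecoregion, biome,
                              bound = "point") {
  m <- codes(grid)
  function(landUse, intensity) {
    r <- matrix(0, nrow(m), ncol(m))
    for (k in seq_len(nrow(legend))) {
      sel <- m == legend$code[k]
      if (!any(sel)) next
      rk <- .classResistance(params, group, ecoregion, biome,
                             landUse, intensity,
                             legend$land_use[k], legend$intensity[k], bound)
      r[sel] <- if (is.na(rk)) 1 else rk
    }
    r
  }
}

# Pool intensity levels: legend classes of one land use collapse to "all";
# rr estimates combine by inverse-variance-weighted mean.
.poolLegend <- function(legend) {
  pooled <- legend
  anthro <- pooled$intensity != .NATURAL
  pooled$intensity[anthro] <- "all"
  pooled
}

.poolParams <- function(params) {
  rr <- params@rr
  keys <- unique(rr[, c("group", "land_use")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rr$group == keys$group[i] & rr$land_use == keys$land_use[i]
    w <- 1 / rr$se[sel]^2
    if (any(!is.finite(w))) w <- rep(1, sum(sel))
    data.frame(group = keys$group[i], land_use = keys$land_use[i],
               intensity = "all",
               rr = sum(w * rr$rr[sel]) / sum(w),
               se = sqrt(1 / sum(w)),
               lo = sum(w * rr$lo[sel]) / sum(w),
               hi = sum(w * rr$hi[sel]) / sum(w),
               stringsAsFactors = FALSE)
  })
  params@rr <- do.call(rbind, out)
  params
}

#' Habitat state of an ecoregion for one species group
#'
#' Computes, per (land use, intensity) class present in the landscape, the
#' total area A, the equivalent connected area ECA and the habitat affinity
#' h, and sums their products into the suitable connected area
#' `H = sum(h * ECA)`. The fully natural reference has `H0 = A_j`, the
#' ecoregion area.
#'
#' @param grid a [LandscapeGrid-class].
#' @param legend legend data.frame.
#' @param params a [ParamSet-class].
#' @param group species group.
#' @param ecoregion,biome identifiers used to key the parameter tables.
#' @param options engine options from [cfOptions()].
#' @return A list with elements `classes` (data.frame land_use, intensity,
#'   A, ECA, h), `A_j`, `H0`, `H1`, `z` and `d_med`.
#' @export
habitatState <- function(grid, legend, params, group, ecoregion, biome,
                         options = cfOptions()) {
  if (!options$intensity) {
    legend <- .poolLegend(legend)
    params <- .poolParams(params)
  }
  z <- .zValue(params, group, biome)
  if (is.na(z)) stop("no z-value for (", group, ", ", biome, ")")
  disp <- params@dispersal
  i <- which(disp$group == group & disp$ecoregion == ecoregion)
  if (!length(i)) stop("no dispersal distance for (", group, ", ",
                       ecoregion, ")")
  dMed <- disp$d_med[i[1]]
  resFun <- if (options$fragmentation) {
    .resistanceFunFor(grid, legend, params, group, ecoregion, biome,
                      options$rrBound)
  } else {
    NULL
  }
  conn <- classConnectivity(grid, legend, dMed, resFun,
                            connectivity = options$connectivity,
                            cutoff = options$cutoff,
                            fragmentation = options$fragmentation)
  conn$h <- vapply(seq_len(nrow(conn)), function(k) {
    .affinity(params, group, ecoregion, biome, conn$land_use[k],
              conn$intensity[k], options$rrBound)
  }, 0)
  A_j <- sum(conn$A)
  keep <- !is.na(conn$h)
  H1 <- sum(conn$h[keep] * conn$ECA[keep])
  list(classes = conn, A_j = A_j, H0 = A_j, H1 = min(H1, A_j), z = z,
       d_med = dMed, group = group, ecoregion = ecoregion, biome = biome)
}

#' Regional species loss from the species-habitat relationship
#'
#' `RSL = 1 - (H1/H0)^z`: the potentially disappeared fraction of species
#' of an ecoregion when its suitable connected area drops from the natural
#' reference H0 to H1.
#'
#' @param H1 current suitable connected area (m^2), 0 <= H1 <= H0.
#' @param H0 reference suitable connected area (m^2), > 0.
#' @param z species-area slope in (0, 1).
#' @return RSL in \[0, 1\] (dimensionless, conventionally called PDF).
#' @examples
#' regionalSpeciesLoss(0.5, 1, 0.25)
#' @export
regionalSpeciesLoss <- function(H1, H0, z) {
  if (any(z <= 0 | z >= 1)) stop("z must lie in (0, 1)")
  if (any(H0 <= 0)) stop("H0 must be positive")
  if (any(H1 > H0 * (1 + 1e-9))) stop("H1 must not exceed H0")
  if (any(H1 < 0)) stop("H1 must be >= 0")
  1 - (pmin(H1, H0) / H0)^z
}

#' Allocation factors across anthropogenic classes
#'
#' Shares out the regional species loss over the land-use classes in
#' proportion to their connected-habitat deficit, `A - h * ECA`, i.e. area
#' times one minus the connectivity-discounted effective affinity
#' `h * ECA / A`. A class with full affinity and unfragmented patches is
#' harmless and receives 0; without fragmentation the weight reduces to
#' the plain `A * (1 - h)`.
#'
#' @param state a habitat state from [habitatState()].
#' @return data.frame land_use, intensity, a; `a` sums to 1 over
#'   anthropogenic classes whenever any class has a habitat deficit (all
#'   zero, with a warning, in a fully natural or fully harmless
#'   landscape).
#' @export
allocationFactors <- function(state) {
  cls <- state$classes
  anthro <- cls[cls$land_use != .NATURAL & !is.na(cls$h), , drop = FALSE]
  if (!nrow(anthro)) {
    warning("no anthropogenic class: allocation undefined")
    return(data.frame(land_use = character(), intensity = character(),
                      a = numeric()))
  }
  w <- anthro$A - anthro$h * anthro$ECA
  if (sum(w) == 0) {
    warning("all classes fully suitable: allocation set to 0")
    a <- rep(0, nrow(anthro))
  } else {
    a <- w / sum(w)
  }
  data.frame(land_use = anthro$land_use, intensity = anthro$intensity, a = a,
             stringsAsFactors = FALSE)
}

#' Average occupation characterization factor
#'
#' The regional species loss allocated to a class and divided by the
#' class's area: `CF = RSL * a / A_im`, in PDF per m^2 occupied.
#'
#' @param state habitat state from [habitatState()].
#' @param landUse,intensity the class.
#' @return CF in PDF/m^2 (NA when the class is absent).
#' @export
cfOccupationAverage <- function(state, landUse, intensity) {
  cls <- state$classes
  i <- which(cls$land_use == landUse & cls$intensity == intensity)
  if (!length(i) || cls$A[i] <= 0) return(NA_real_)
  rsl <- regionalSpeciesLoss(state$H1, state$H0, state$z)
  alloc <- allocationFactors(state)
  j <- which(alloc$land_use == landUse & alloc$intensity == intensity)
  if (!length(j)) return(NA_real_)
  rsl * alloc$a[j] / cls$A[i]
}

#' Marginal occupation characterization factor
#'
#' The partial derivative of regional species loss with respect to the
#' class's area, evaluated by a central finite difference with relative
#' step `relStep`. The marginal exchange is valued with the landscape's
#' connectivity structure frozen: one m^2 converted removes one m^2 of
#' suitable natural habitat and adds habitat at the class's
#' connectivity-discounted effective affinity `h * ECA / A` (the class
#' expands proportionally across its patches), so
#' `dH = (h * ECA / A - 1) dA`. In the fragmentation-free limit this
#' reproduces the analytic derivative of the species-habitat relationship,
#' and together with the matching allocation weights it keeps the marginal
#' CF at or above the average CF whenever the natural matrix is connected
#' (see the methods vignette).
#'
#' @param state habitat state from [habitatState()].
#' @param landUse,intensity the class.
#' @param relStep relative finite-difference step.
#' @return CF in PDF/m^2 (NA when the class is absent). One-sided when no
#'   natural habitat remains (with a warning).
#' @export
cfOccupationMarginal <- function(state, landUse, intensity,
                                 relStep = 1e-4) {
  cls <- state$classes
  i <- which(cls$land_use == landUse & cls$intensity == intensity)
  if (!length(i) || cls$A[i] <= 0) return(NA_real_)
  h_im <- cls$h[i]
  if (is.na(h_im)) return(NA_real_)
  A_im <- cls$A[i]
  hEff <- h_im * cls$ECA[i] / A_im  # connectivity-discounted affinity
  nat <- which(cls$land_use == .NATURAL)
  A_nat <- if (length(nat)) cls$A[nat] else 0
  Hfun <- function(eps) {
    # marginal exchange at frozen connectivity: dH = (hEff - 1) dA
    state$H1 + (hEff - 1) * eps * A_im
  }
  rsl <- function(eps) {
    regionalSpeciesLoss(min(max(Hfun(eps), 0), state$H0), state$H0, state$z)
  }
  if (A_nat > 0) {
    (rsl(relStep) - rsl(-relStep)) / (2 * relStep * A_im)
  } else {
    warning("no natural habitat left: one-sided difference")
    (rsl(0) - rsl(-relStep)) / (relStep * A_im)
  }
}

#' Transformation characterization factor
#'
#' Converts an occupation CF into a transformation CF by integrating a
#' linear recovery over the regeneration time: `CF_tra = 0.5 * t * CF_occ`,
#' in PDF.yr/m^2 transformed.
#'
#' @param cfOcc occupation CF (PDF/m^2).
#' @param t regeneration time in years (> 0).
#' @return Transformation CF in PDF.yr/m^2.
#' @export
cfTransformation <- function(cfOcc, t) {
  if (any(t < 0)) stop("regeneration time must be >= 0")
  0.5 * t * cfOcc
}

#' Regional-to-global conversion
#'
#' Weights a regional CF (relative extirpations) by the ecoregion's global
#' extinction probability to express relative global extinctions.
#'
#' @param cfRegional regional CF.
#' @param gep global extinction probability in \[0, 1\].
#' @return Global CF.
#' @export
toGlobalCF <- function(cfRegional, gep) {
  if (any(gep < 0 | gep > 1)) stop("gep must lie in [0, 1]")
  cfRegional * gep
}

.regenTime <- function(params, group, biome, landUse) {
  t <- params@regeneration
  i <- which(t$group == group & t$biome == biome & t$land_use == landUse)
  if (!length(i)) return(NA_real_)
  t$t_reg[i[1]]
}

.gep <- function(params, group, ecoregion) {
  g <- params@geps
  i <- which(g$group == group & g$ecoregion == ecoregion)
  if (!length(i)) return(NA_real_)
  g$gep[i[1]]
}

.emptyCfs <- function() {
  data.frame(ecoregion = character(), group = character(),
             land_use = character(), intensity = character(),
             approach = character(), extent = character(),
             kind = character(), value = numeric(), unit = character(),
             proxy_flag = logical(), rel_weighted_sd = numeric(),
             stringsAsFactors = FALSE)
}

.emptyGaps <- function() {
  data.frame(ecoregion = character(), group = character(),
             land_use = character(), intensity = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Characterization factors for one ecoregion
#'
#' Runs the full pipeline for every species group and every anthropogenic
#' class present: habitat state (areas, ECAs, affinities), regional species
#' loss, allocation, average and marginal occupation CFs, transformation
#' CFs via regeneration times, and global CFs via GEPs. Classes or
#' parameters that are missing yield gap records instead of CF rows.
#'
#' @param grid a [LandscapeGrid-class].
#' @param legend legend data.frame.
#' @param params a [ParamSet-class].
#' @param ecoregion,biome identifiers.
#' @param groups species groups to compute (default: all in `params`).
#' @param options engine options from [cfOptions()].
#' @return A list with `cfs` (CF records: ecoregion, group, land_use,
#'   intensity, approach, extent, kind, value, unit, proxy_flag,
#'   rel_weighted_sd) and `gaps` (missing combinations with reasons).
#' @export
computeEcoregionCFs <- function(grid, legend, params, ecoregion, biome,
                                groups = NULL, options = cfOptions()) {
  if (is.null(groups)) groups <- params@groups$group
  useLegend <- if (options$intensity) legend else .poolLegend(legend)
  anthroLegend <- unique(useLegend[useLegend$land_use != .NATURAL,
                                   c("land_use", "intensity")])
  cfs <- list(); gaps <- list()
  note <- function(group, lu, int, reason) {
    gaps[[length(gaps) + 1]] <<- data.frame(
      ecoregion = ecoregion, group = group, land_use = lu, intensity = int,
      reason = reason, stringsAsFactors = FALSE)
  }
  for (group in groups) {
    state <- habitatState(grid, legend, params, group, ecoregion, biome,
                          options)
    cls <- state$classes
    if (!any(cls$land_use != .NATURAL)) {
      note(group, NA_character_, NA_character_, "no anthropogenic class")
      next
    }
    gep <- .gep(params, group, ecoregion)
    for (k in seq_len(nrow(anthroLegend))) {
      lu <- anthroLegend$land_use[k]; int <- anthroLegend$intensity[k]
      i <- which(cls$land_use == lu & cls$intensity == int)
      if (!length(i)) {
        note(group, lu, int, "class absent from ecoregion")
        next
      }
      if (is.na(cls$h[i])) {
        note(group, lu, int, "missing affinity parameters")
        next
      }
      avg <- cfOccupationAverage(state, lu, int)
      marg <- cfOccupationMarginal(state, lu, int, options$fdStep)
      t_reg <- .regenTime(params, group, biome, lu)
      for (approach in c("average", "marginal")) {
        occ <- if (approach == "average") avg else marg
        vals <- list(occupation = occ)
        if (is.na(t_reg)) {
          note(group, lu, int, "missing regeneration time")
        } else {
          vals$transformation <- cfTransformation(occ, t_reg)
        }
        for (kind in names(vals)) {
          unit <- if (kind == "occupation") "PDF/m2" else "PDF*yr/m2"
          cfs[[length(cfs) + 1]] <- data.frame(
            ecoregion = ecoregion, group = group, land_use = lu,
            intensity = int, approach = approach, extent = "regional",
            kind = kind, value = vals[[kind]], unit = unit,
            proxy_flag = FALSE, rel_weighted_sd = NA_real_,
            stringsAsFactors = FALSE)
          if (is.na(gep)) {
            note(group, lu, int, "missing GEP")
          } else {
            cfs[[length(cfs) + 1]] <- data.frame(
              ecoregion = ecoregion, group = group, land_use = lu,
              intensity = int, approach = approach, extent = "global",
              kind = kind, value = toGlobalCF(vals[[kind]], gep),
              unit = unit, proxy_flag = FALSE, rel_weighted_sd = NA_real_,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  cfs <- if (length(cfs)) do.call(rbind, cfs) else .emptyCfs()
  gaps <- if (length(gaps)) unique(do.call(rbind, gaps)) else .emptyGaps()
  list(cfs = .sortCfs(cfs), gaps = gaps)
}

.sortCfs <- function(cfs) {
  if (!nrow(cfs)) return(cfs)
  o <- order(cfs$ecoregion, cfs$group, cfs$land_use, cfs$intensity,
             cfs$approach, cfs$extent, cfs$kind)
  out <- cfs[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Characterization factors for a whole synthetic world
#'
#' Applies [computeEcoregionCFs()] to every ecoregion of a
#' [SyntheticWorld-class].
#'
#' @param world a [SyntheticWorld-class].
#' @param groups species groups (default all).
#' @param options engine options from [cfOptions()].
#' @return A list with combined `cfs` and `gaps` tables.
#' @export
computeWorldCFs <- function(world, groups = NULL, options = cfOptions()) {
  eco <- ecoregionTable(world)
  res <- lapply(seq_len(nrow(eco)), function(i) {
    computeEcoregionCFs(landscapes(world)[[eco$ecoregion[i]]],
                        classLegend(world), worldParams(world),
                        eco$ecoregion[i], eco$biome[i], groups, options)
  })
  list(cfs = .sortCfs(do.call(rbind, lapply(res, `[[`, "cfs"))),
       gaps = do.call(rbind, lapply(res, `[[`, "gaps")))
}
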