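#' Write a landscape as an ESRI ASCII grid
#'
#' @param grid a [LandscapeGrid-class].
#' @param path output path (conventionally .asc).
#' @return The path, invisibly.
#' @export
writeAsciiGrid <- function(grid, path) {
  m <- codes(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", format(cellSize(grid), scientific = FALSE)),
    paste("NODATA_value", nodataCode(grid))), con)
  apply(m, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to the .asc file.
#' @param ecoregionId identifier for the resulting grid (default: file
#'   name without extension).
#' @return A [LandscapeGrid-class].
#' @export
readAsciiGrid <- function(path, ecoregionId = NULL) {
  if (!file.exists(path)) stop("no such raster: ", path)
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header))) {
    stop("malformed ASCII grid header in ", path)
  }
  vals <- as.integer(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  nr <- header$nrows; nc <- header$ncols
  if (length(vals) != nr * nc) stop("cell count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.null(ecoregionId)) {
    ecoregionId <- sub("\\.[^.]*$", "", basename(path))
  }
  nodata <- if (!is.null(header$nodata_value)) {
    as.integer(header$nodata_value)
  } else {
    -9999L
  }
  landscapeGrid(m, header$cellsize, ecoregionId, nodata)
}

#' Read and validate a landscape against a legend
#'
#' @param path path to an ESRI ASCII grid of integer class codes.
#' @param legend legend data.frame; any raster code outside the legend
#'   raises an error naming the offending codes.
#' @param ecoregionId optional identifier.
#' @return A validated [LandscapeGrid-class].
#' @export
readLandscape <- function(path, legend, ecoregionId = NULL) {
  grid <- readAsciiGrid(path, ecoregionId)
  .checkCodes(grid, legend)
  grid
}

.bundleFiles <- c(legend = "legend.csv", rr = "rr.csv", z = "z.csv",
                  dispersal = "dispersal.csv",
                  suitability = "suitability.csv", shared = "shared.csv",
                  regeneration = "regeneration.csv", geps = "geps.csv",
                  groups = "groups.csv", ecoregions = "ecoregions.csv",
                  countries = "countries.csv", overlaps = "overlaps.csv")

#' Write a synthetic world as a plain-text input bundle
#'
#' Emits one ASCII grid per ecoregion plus the legend and parameter CSVs
#' and a config.yaml holding the generating spec, i.e. everything
#' [runCompute()] needs.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeWorldBundle <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- worldParams(world)
  tables <- list(legend = classLegend(world), rr = p@rr, z = p@z,
                 dispersal = p@dispersal, suitability = p@suitability,
                 shared = p@shared, regeneration = p@regeneration,
                 geps = p@geps, groups = p@groups,
                 ecoregions = ecoregionTable(world),
                 countries = countryTable(world),
                 overlaps = overlapTable(world))
  for (nm in names(tables)) {
    write.csv(tables[[nm]], file.path(dir, .bundleFiles[[nm]]),
              row.names = FALSE)
  }
  for (eco in names(landscapes(world))) {
    writeAsciiGrid(landscapes(world)[[eco]],
                   file.path(dir, paste0("landscape_", eco, ".asc")))
  }
  spec <- world@spec
  spec$groups <- NULL  # lives in groups.csv
  yaml::write_yaml(spec, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read an input bundle back into a SyntheticWorld
#'
#' @param dir bundle directory written by [writeWorldBundle()].
#' @return A [SyntheticWorld-class].
#' @export
readWorldBundle <- function(dir) {
  paths <- file.path(dir, .bundleFiles)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("bundle incomplete, missing: ",
         paste(.bundleFiles[missing], collapse = ", "))
  }
  tb <- lapply(paths, read.csv, stringsAsFactors = FALSE)
  names(tb) <- names(.bundleFiles)
  spec <- yaml::read_yaml(file.path(dir, "config.yaml"))
  legend <- tb$legend
  landscapes <- lapply(tb$ecoregions$ecoregion, function(eco) {
    readLandscape(file.path(dir, paste0("landscape_", eco, ".asc")),
                  legend, eco)
  })
  names(landscapes) <- tb$ecoregions$ecoregion
  params <- paramSet(rr = tb$rr, z = tb$z, dispersal = tb$dispersal,
                     suitability = tb$suitability, shared = tb$shared,
                     regeneration = tb$regeneration, geps = tb$geps,
                     groups = tb$groups)
  new("SyntheticWorld", spec = spec, legend = legend,
      ecoregions = tb$ecoregions, countries = tb$countries,
      overlaps = tb$overlaps, landscapes = landscapes, params = params)
}

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  config
}

#' Compute ecoregion CFs from an input bundle
#'
#' Validates the configuration, loads the bundle, runs the CF engine under
#' the requested variant and writes `cfs.csv` and `gaps.csv` to the output
#' directory. Outputs are sorted and deterministic: re-running the same
#' configuration reproduces them byte for byte.
#'
#' @param config a list (or path to a YAML file) with keys `bundle`
#'   (bundle directory), `out_dir`, and optionally `variant` (default
#'   "default"), `groups` and `seed`.
#' @return Invisibly, a list with the output paths and the tables.
#' @export
runCompute <- function(config) {
  config <- .readConfig(config)
  if (is.null(config$bundle) || !dir.exists(config$bundle)) {
    stop("config error: 'bundle' must name an existing directory")
  }
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  variant <- if (is.null(config$variant)) "default" else config$variant
  variantOptions(variant)  # validates the name before any work
  world <- readWorldBundle(config$bundle)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  res <- computeWorldCFs(world, groups = config$groups,
                         options = variantOptions(variant))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfPath <- file.path(config$out_dir, "cfs.csv")
  gapPath <- file.path(config$out_dir, "gaps.csv")
  write.csv(res$cfs, cfPath, row.names = FALSE)
  write.csv(res$gaps, gapPath, row.names = FALSE)
  for (i in seq_len(nrow(res$gaps))) {
    message("gap: ", paste(res$gaps[i, ], collapse = " / "))
  }
  invisible(list(cfs = cfPath, gaps = gapPath, tables = res))
}

# --- proxy chain -----------------------------------------------------------

# Fill missing (ecoregion, group, class) CFs using, in order: the nearest
# intensity sibling in the same ecoregion, the biome average of native
# donors, and (for missing GEPs) the biome GEP-density proxy. Native CFs
# are never overwritten; every proxy row is flagged.
fillCfGaps <- function(world, cfs, gaps) {
  params <- worldParams(world)
  eco <- ecoregionTable(world)
  out <- cfs
  absent <- gaps[gaps$reason == "class absent from ecoregion", , drop = FALSE]
  for (i in seq_len(nrow(absent))) {
    ecoId <- absent$ecoregion[i]; g <- absent$group[i]
    lu <- absent$land_use[i]; int <- absent$intensity[i]
    biome <- eco$biome[eco$ecoregion == ecoId][1]
    gep <- .gep(params, g, ecoId)
    if (is.na(gep)) {
      donors <- merge(params@geps[params@geps$group == g, ],
                      eco[eco$biome == biome, c("ecoregion", "area")])
      gep <- proxyGEP(donors$gep, donors$area,
                      eco$area[eco$ecoregion == ecoId][1])
    }
    for (approach in c("average", "marginal")) {
      for (kind in c("occupation", "transformation")) {
        native <- out[!out$proxy_flag & out$group == g &
                      out$land_use == lu & out$approach == approach &
                      out$kind == kind & out$extent == "regional", ,
                      drop = FALSE]
        # 1. intensity sibling within the ecoregion
        sib <- native[native$ecoregion == ecoId, , drop = FALSE]
        val <- NA_real_
        if (nrow(sib)) {
          hFor <- function(int2) .affinity(params, g, ecoId, biome, lu, int2)
          sibs <- data.frame(intensity = sib$intensity, value = sib$value,
                             h = vapply(sib$intensity, hFor, 0))
          hT <- hFor(int)
          px <- if (is.na(hT)) NULL else proxyIntensity(sibs, int, hT)
          if (!is.null(px)) val <- px$value
        }
        # 2. biome average of native donors of the same class
        if (is.na(val)) {
          donors <- native[native$intensity == int &
                           native$ecoregion %in%
                             eco$ecoregion[eco$biome == biome], ,
                           drop = FALSE]
          val <- proxyBiome(donors$value)
        }
        if (is.na(val)) next  # stays missing (e.g. empty biome)
        unit <- if (kind == "occupation") "PDF/m2" else "PDF*yr/m2"
        add <- data.frame(ecoregion = ecoId, group = g, land_use = lu,
                          intensity = int, approach = approach,
                          extent = "regional", kind = kind, value = val,
                          unit = unit, proxy_flag = TRUE,
                          rel_weighted_sd = NA_real_,
                          stringsAsFactors = FALSE)
        out <- rbind(out, add)
        if (!is.na(gep)) {
          add$extent <- "global"
          add$value <- toGlobalCF(val, gep)
          out <- rbind(out, add)
        }
      }
    }
  }
  .sortCfs(out)
}

# Per-(ecoregion, class) land-use areas, for the alternative global
# weighting.
classAreas <- function(world) {
  legend <- classLegend(world)
  out <- list()
  for (eco in names(landscapes(world))) {
    m <- codes(landscapes(world)[[eco]])
    cs <- cellSize(landscapes(world)[[eco]])
    for (k in seq_len(nrow(legend))) {
      n <- sum(m == legend$code[k])
      if (n == 0) next
      out[[length(out) + 1]] <- data.frame(
        ecoregion = eco, land_use = legend$land_use[k],
        intensity = legend$intensity[k], A = n * cs^2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Aggregate ecoregion CFs to countries and the globe
#'
#' Adds the equal-weight taxonomic aggregate ("aggregated" group), then
#' aggregates every (group, class, approach, extent, kind) combination to
#' the country level (ecoregion-in-country overlap areas as weights) and
#' to the global level (ecoregion areas; optionally land-use areas for
#' native rows), reporting relative weighted standard deviations.
#' Countries without ecoregion overlap are filled from their three nearest
#' neighbours with pooled SDs.
#'
#' @param world a [SyntheticWorld-class].
#' @param cfs CF table from [computeWorldCFs()], possibly proxy-filled.
#' @param weighting global weighting: "ecoregion" area (default, required
#'   for proxy rows) or "landuse" area.
#' @return list with `country` and `global` CF tables (scope column
#'   included).
#' @export
aggregateWorldCFs <- function(world, cfs, weighting = c("ecoregion",
                                                        "landuse")) {
  weighting <- match.arg(weighting)
  eco <- ecoregionTable(world)
  # taxonomic aggregation per ecoregion and class
  keys <- unique(cfs[, c("ecoregion", "land_use", "intensity", "approach",
                         "extent", "kind", "unit")])
  taxa <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- cfs$ecoregion == keys$ecoregion[i] &
      cfs$land_use == keys$land_use[i] &
      cfs$intensity == keys$intensity[i] &
      cfs$approach == keys$approach[i] & cfs$extent == keys$extent[i] &
      cfs$kind == keys$kind[i]
    v <- setNames(cfs$value[sel], cfs$group[sel])
    if (length(v) < 2) next
    agg <- suppressWarnings(aggregateTaxa(v))
    taxa[[length(taxa) + 1]] <- cbind(
      keys[i, , drop = FALSE],
      data.frame(group = "aggregated", value = agg$value,
                 proxy_flag = any(cfs$proxy_flag[sel]),
                 rel_weighted_sd = NA_real_, stringsAsFactors = FALSE))
  }
  withTaxa <- rbind(cfs,
                    if (length(taxa)) do.call(rbind, taxa)[, names(cfs)])
  areas <- if (weighting == "landuse") classAreas(world) else NULL

  spatial <- function(scopeTable) {
    keys <- unique(withTaxa[, c("group", "land_use", "intensity",
                                "approach", "extent", "kind", "unit")])
    rows <- list()
    for (s in unique(scopeTable$scope)) {
      members <- scopeTable[scopeTable$scope == s, , drop = FALSE]
      for (i in seq_len(nrow(keys))) {
        sel <- withTaxa$group == keys$group[i] &
          withTaxa$land_use == keys$land_use[i] &
          withTaxa$intensity == keys$intensity[i] &
          withTaxa$approach == keys$approach[i] &
          withTaxa$extent == keys$extent[i] &
          withTaxa$kind == keys$kind[i] &
          withTaxa$ecoregion %in% members$ecoregion
        if (!any(sel)) next
        sub <- withTaxa[sel, , drop = FALSE]
        w <- members$weight[match(sub$ecoregion, members$ecoregion)]
        if (!is.null(areas)) {
          aSel <- areas$land_use == keys$land_use[i] &
            areas$intensity == keys$intensity[i]
          aW <- areas$A[aSel][match(sub$ecoregion, areas$ecoregion[aSel])]
          usable <- !is.na(aW) & !sub$proxy_flag
          if (any(usable)) {
            sub <- sub[usable, , drop = FALSE]
            w <- aW[usable]
          }
        }
        if (sum(w) == 0) next
        ag <- aggregateSpatial(sub$value, w)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(scope = s, stringsAsFactors = FALSE),
          keys[i, , drop = FALSE],
          data.frame(value = ag$value, sd = ag$sd, rel_weighted_sd = ag$rel_sd,
                     proxy_flag = any(sub$proxy_flag),
                     stringsAsFactors = FALSE))
      }
    }
    if (!length(rows)) return(NULL)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$scope, out$group, out$land_use, out$intensity,
              out$approach, out$extent, out$kind), , drop = FALSE]
  }

  ov <- overlapTable(world)
  country <- spatial(data.frame(scope = ov$country,
                                ecoregion = ov$ecoregion,
                                weight = ov$area,
                                stringsAsFactors = FALSE))
  # countries without any ecoregion: nearest-3 proxy with pooled SDs
  missingCountries <- setdiff(countryTable(world)$country,
                              unique(ov$country))
  if (length(missingCountries) && !is.null(country)) {
    ct <- countryTable(world)
    extra <- list()
    for (mc in missingCountries) {
      target <- c(ct$x[ct$country == mc], ct$y[ct$country == mc])
      keys <- unique(country[, c("group", "land_use", "intensity",
                                 "approach", "extent", "kind", "unit")])
      for (i in seq_len(nrow(keys))) {
        sel <- country$group == keys$group[i] &
          country$land_use == keys$land_use[i] &
          country$intensity == keys$intensity[i] &
          country$approach == keys$approach[i] &
          country$extent == keys$extent[i] & country$kind == keys$kind[i]
        cand <- country[sel, , drop = FALSE]
        cand <- merge(cand, ct, by.x = "scope", by.y = "country")
        if (!nrow(cand)) next
        cand <- data.frame(country = cand$scope, x = cand$x, y = cand$y,
                           value = cand$value, sd = cand$sd,
                           stringsAsFactors = FALSE)
        px <- suppressWarnings(proxyCountry(target, cand))
        extra[[length(extra) + 1]] <- cbind(
          data.frame(scope = mc, stringsAsFactors = FALSE),
          keys[i, , drop = FALSE],
          data.frame(value = px$value, sd = px$sd,
                     rel_weighted_sd = if (px$value != 0) px$sd / px$value
                                       else NA_real_,
                     proxy_flag = TRUE, stringsAsFactors = FALSE))
      }
    }
    if (length(extra)) country <- rbind(country, do.call(rbind, extra))
  }
  globalTab <- spatial(data.frame(scope = "global",
                                  ecoregion = eco$ecoregion,
                                  weight = eco$area,
                                  stringsAsFactors = FALSE))
  list(country = country, global = globalTab)
}

#' Aggregate a computed CF table and write country/global CSVs
#'
#' Reads the ecoregion CF table produced by [runCompute()], applies the
#' proxy chain to the recorded gaps, aggregates across taxa and space and
#' writes `country_cfs.csv` and `global_cfs.csv`.
#'
#' @param config list or YAML path with keys `bundle`, `cf_dir` (directory
#'   holding cfs.csv and gaps.csv from [runCompute()]), `out_dir`, and
#'   optionally `weighting` ("ecoregion" or "landuse").
#' @return Invisibly, a list with the output paths and tables.
#' @export
runAggregate <- function(config) {
  config <- .readConfig(config)
  for (key in c("bundle", "cf_dir", "out_dir")) {
    if (is.null(config[[key]])) stop("config error: '", key, "' is required")
  }
  cfPath <- file.path(config$cf_dir, "cfs.csv")
  gapPath <- file.path(config$cf_dir, "gaps.csv")
  if (!file.exists(cfPath)) stop("config error: ", cfPath, " not found")
  world <- readWorldBundle(config$bundle)
  cfs <- read.csv(cfPath, stringsAsFactors = FALSE)
  gaps <- if (file.exists(gapPath)) {
    read.csv(gapPath, stringsAsFactors = FALSE)
  } else {
    .emptyGaps()
  }
  weighting <- if (is.null(config$weighting)) "ecoregion" else config$weighting
  filled <- fillCfGaps(world, cfs, gaps)
  agg <- aggregateWorldCFs(world, filled, weighting)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  countryPath <- file.path(config$out_dir, "country_cfs.csv")
  globalPath <- file.path(config$out_dir, "global_cfs.csv")
  write.csv(if (is.null(agg$country)) data.frame() else agg$country,
            countryPath, row.names = FALSE)
  write.csv(if (is.null(agg$global)) data.frame() else agg$global,
            globalPath, row.names = FALSE)
  invisible(list(country = countryPath, global = globalPath, tables = agg,
                 filled = filled))
}
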