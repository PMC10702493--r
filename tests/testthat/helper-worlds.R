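# Small synthetic worlds shared across tests: two species groups (one per
# kingdom) and compact grids keep the suite fast while exercising both
# parametrization routes.

tinyGroups <- data.frame(group = c("plants", "birds"),
                         kingdom = c("plant", "animal"),
                         stringsAsFactors = FALSE)

tinySpec <- function(seed = 1, nEcoregions = 2, dim = c(16, 16), ...) {
  worldSpec(nEcoregions = nEcoregions, dim = dim, cellSize = 1000,
            nBiomes = 2, nCountries = 3,
            landUses = list(cropland = c("minimal", "light", "intense"),
                            pasture = c("minimal", "intense"),
                            urban = c("light", "intense")),
            groups = tinyGroups,
            dispersalRanges = list(plants = c(500, 3000),
                                   birds = c(5000, 20000)),
            seed = seed, ...)
}

# A minimal hand-built habitat state for closed-form checks: one
# anthropogenic class (affinity h) plus natural habitat, no fragmentation
# (ECA = A).
flatState <- function(A_j = 1e8, A_used = 3e7, h = 0, z = 0.25) {
  classes <- data.frame(
    land_use = c("natural", "cropland"),
    intensity = c("natural", "intense"),
    A = c(A_j - A_used, A_used),
    ECA = c(A_j - A_used, A_used),
    h = c(1, h), stringsAsFactors = FALSE)
  list(classes = classes, A_j = A_j, H0 = A_j,
       H1 = (A_j - A_used) + h * A_used, z = z,
       d_med = 1000, group = "plants", ecoregion = "eco1", biome = "biome1")
}
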