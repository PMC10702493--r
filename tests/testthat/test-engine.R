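test_that("regional species loss honours the power-law limits", {
  expect_equal(regionalSpeciesLoss(1, 1, 0.25), 0)
  expect_equal(regionalSpeciesLoss(0, 1, 0.25), 1)
  expect_equal(regionalSpeciesLoss(0.5, 1, 0.25), 1 - 0.5^0.25)
  expect_error(regionalSpeciesLoss(1.1, 1, 0.25), "exceed")
  expect_error(regionalSpeciesLoss(0.5, 1, 1.5), "\\(0, 1\\)")
  # monotone non-increasing in H1
  H <- seq(0, 1, by = 0.05)
  expect_true(all(diff(regionalSpeciesLoss(H, 1, 0.3)) <= 0))
})

test_that("allocation weights classes by area times habitat deficit", {
  st <- flatState()
  st$classes <- data.frame(
    land_use = c("natural", "cropland", "pasture"),
    intensity = c("natural", "intense", "minimal"),
    A = c(4e7, 3e7, 3e7), ECA = c(4e7, 3e7, 3e7),
    h = c(1, 0, 0.5), stringsAsFactors = FALSE)
  a <- allocationFactors(st)
  expect_equal(a$a, c(2 / 3, 1 / 3))
  expect_equal(sum(a$a), 1)

  # a class with full affinity gets zero
  st$classes$h <- c(1, 0.4, 1)
  a <- allocationFactors(st)
  expect_equal(a$a[a$land_use == "pasture"], 0)

  st$classes <- st$classes[1, , drop = FALSE]
  expect_warning(allocationFactors(st), "no anthropogenic class")
})

test_that("average occupation CF equals RSL * a / A on a hand state", {
  st <- flatState(A_j = 1e8, A_used = 1e8, h = 0)  # class fills ecoregion
  st$classes <- st$classes[st$classes$land_use != "natural", , drop = FALSE]
  st$classes$A <- 1e8; st$classes$ECA <- 1e8
  st$H1 <- 0
  expect_equal(cfOccupationAverage(st, "cropland", "intense"), 1 / 1e8)

  st2 <- flatState(A_j = 2e8, A_used = 5e7, h = 0.3, z = 0.2)
  rsl <- 1 - ((2e8 - 5e7 + 0.3 * 5e7) / 2e8)^0.2
  expect_equal(cfOccupationAverage(st2, "cropland", "intense"),
               rsl * 1 / 5e7, tolerance = 1e-12)
  expect_true(is.na(cfOccupationAverage(st2, "urban", "light")))
})

test_that("marginal CF matches the closed-form derivative without fragmentation", {
  for (z in c(0.15, 0.25, 0.35)) {
    for (share in c(0.1, 0.3, 0.6)) {
      A_j <- 1e8; A <- share * A_j
      st <- flatState(A_j = A_j, A_used = A, h = 0, z = z)
      got <- cfOccupationMarginal(st, "cropland", "intense")
      want <- (z / A_j) * ((A_j - A) / A_j)^(z - 1)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
  # a fully suitable class has no marginal impact
  st <- flatState(h = 1)
  expect_equal(cfOccupationMarginal(st, "cropland", "intense"), 0,
               tolerance = 1e-15)
})

test_that("marginal is one-sided with a warning when nothing natural remains", {
  st <- flatState(A_j = 1e8, A_used = 1e8, h = 0.2)
  st$classes <- st$classes[st$classes$land_use != "natural", , drop = FALSE]
  st$H1 <- 0.2 * 1e8
  expect_warning(v <- cfOccupationMarginal(st, "cropland", "intense"),
                 "one-sided")
  expect_true(is.finite(v))
})

test_that("transformation CFs integrate linear regeneration", {
  expect_equal(cfTransformation(2e-12, 100), 1e-10)
  expect_equal(cfTransformation(3e-12, 0), 0)
  expect_equal(cfTransformation(1e-12, 80), 2 * cfTransformation(1e-12, 40))
  expect_error(cfTransformation(1e-12, -1), ">= 0")
})

test_that("global conversion weights by the extinction probability", {
  expect_equal(toGlobalCF(3e-12, 0.004), 1.2e-14)
  expect_equal(toGlobalCF(5e-12, 0), 0)
  expect_equal(toGlobalCF(5e-12, 1), 5e-12)
  expect_error(toGlobalCF(1e-12, 1.2), "\\[0, 1\\]")
})

test_that("one class and one group yield the 8-record cross product", {
  spec <- tinySpec(seed = 5, nEcoregions = 1, dim = c(12, 12))
  w <- genWorld(spec)
  m <- matrix(0L, 12, 12); m[3:6, 3:6] <- 1L  # only cropland minimal
  grid <- landscapeGrid(m, 1000, "eco1")
  res <- computeEcoregionCFs(grid, classLegend(w), worldParams(w),
                             "eco1", "biome1", groups = "plants")
  expect_equal(nrow(res$cfs), 8)
  expect_setequal(unique(res$cfs$approach), c("average", "marginal"))
  expect_setequal(unique(res$cfs$extent), c("regional", "global"))
  expect_setequal(unique(res$cfs$kind), c("occupation", "transformation"))
  expect_true(all(res$cfs$value >= 0))
  # absent classes are reported as gaps, not errors
  expect_true(any(res$gaps$reason == "class absent from ecoregion"))
})

test_that("a fully natural ecoregion emits no CFs and a log entry", {
  spec <- tinySpec(seed = 5, nEcoregions = 1, dim = c(10, 10))
  w <- genWorld(spec)
  grid <- landscapeGrid(matrix(0L, 10, 10), 1000, "eco1")
  res <- computeEcoregionCFs(grid, classLegend(w), worldParams(w),
                             "eco1", "biome1", groups = "plants")
  expect_equal(nrow(res$cfs), 0)
  expect_equal(res$gaps$reason, "no anthropogenic class")
})

test_that("habitat state invariants hold on generated worlds", {
  w <- genWorld(tinySpec(seed = 9))
  eco <- ecoregionTable(w)
  for (g in c("plants", "birds")) {
    st <- habitatState(landscapes(w)[[1]], classLegend(w), worldParams(w),
                       g, eco$ecoregion[1], eco$biome[1])
    expect_lte(st$H1, st$H0)
    expect_equal(st$H0, st$A_j)
    expect_true(all(st$classes$ECA <= st$classes$A + 1e-6))
    expect_true(all(st$classes$h >= 0 & st$classes$h <= 1))
    expect_equal(st$classes$h[st$classes$land_use == "natural"], 1)
  }
})

test_that("disabling fragmentation never lowers H, never raises RSL", {
  for (seed in c(2, 4)) {
    w <- genWorld(tinySpec(seed = seed))
    eco <- ecoregionTable(w)
    for (i in seq_len(nrow(eco))) {
      st1 <- habitatState(landscapes(w)[[i]], classLegend(w), worldParams(w),
                          "plants", eco$ecoregion[i], eco$biome[i])
      st0 <- habitatState(landscapes(w)[[i]], classLegend(w), worldParams(w),
                          "plants", eco$ecoregion[i], eco$biome[i],
                          cfOptions(fragmentation = FALSE))
      expect_gte(st0$H1, st1$H1 - 1e-6)
      expect_lte(regionalSpeciesLoss(st0$H1, st0$H0, st0$z),
                 regionalSpeciesLoss(st1$H1, st1$H0, st1$z) + 1e-12)
    }
  }
})
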