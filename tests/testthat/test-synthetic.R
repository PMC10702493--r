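test_that("class areas hit their targets exactly and shares are feasible", {
  spec <- tinySpec(seed = 21)
  g <- genLandscape(spec, 1)
  m <- codes(g)
  legend <- worldLegend(spec)
  anthroCells <- sum(m != 0)
  expect_equal(anthroCells / length(m), spec$anthroShare, tolerance = 0.05)
  # every anthropogenic class is a whole number of cells; rest is natural
  expect_true(all(as.vector(m) %in% legend$code))
  expect_error(genLandscape(worldSpec(anthroShare = 1.5)), "anthroShare")
})

test_that("phi = 0 grows single patches; phi = 1 scatters cells", {
  spec0 <- tinySpec(seed = 31, phi = 0)
  g0 <- genLandscape(spec0, 1)
  legend <- worldLegend(spec0)
  for (code in setdiff(unique(as.vector(codes(g0))), 0)) {
    row <- legend[legend$code == code, ]
    p <- extractPatches(g0, legend, row$land_use, row$intensity)
    expect_length(p, 1)
  }
  spec1 <- tinySpec(seed = 31, phi = 1)
  g1 <- genLandscape(spec1, 1)
  nPatches <- function(g) {
    sum(vapply(setdiff(unique(as.vector(codes(g))), 0), function(code) {
      row <- legend[legend$code == code, ]
      length(extractPatches(g, legend, row$land_use, row$intensity))
    }, 0))
  }
  expect_gt(nPatches(g1), 3 * nPatches(g0))
})

test_that("generated parameters satisfy the table invariants", {
  spec <- tinySpec(seed = 17)
  p <- genParams(spec)
  expect_s4_class(p, "ParamSet")  # validity ran in the constructor
  rr <- p@rr
  for (g in unique(rr$group)) {
    for (lu in unique(rr$land_use)) {
      sub <- rr[rr$group == g & rr$land_use == lu, ]
      o <- match(sub$intensity, c("minimal", "light", "intense"))
      vals <- sub$rr[order(o)]
      expect_true(all(diff(vals) <= 0))  # minimal >= light >= intense
    }
  }
  expect_true(all(rr$lo <= rr$rr & rr$rr <= rr$hi))
  expect_true(all(p@z$z > 0 & p@z$z < 1))
  expect_true(all(p@dispersal$d_med > 0))
})

test_that("generation is deterministic in the seed", {
  s <- tinySpec(seed = 99)
  expect_identical(codes(genLandscape(s, 2)), codes(genLandscape(s, 2)))
  expect_identical(genParams(s)@rr, genParams(s)@rr)
  expect_identical(genGEPs(s), genGEPs(s))
  expect_identical(genThreatRecords(s), genThreatRecords(s))
  s2 <- tinySpec(seed = 100)
  expect_false(identical(codes(genLandscape(s, 1)),
                         codes(genLandscape(s2, 1))))
})

test_that("GEPs normalize to exactly 1 per species group", {
  for (seed in c(1, 12, 123)) {
    geps <- genGEPs(tinySpec(seed = seed, nEcoregions = 5))
    sums <- tapply(geps$gep, geps$group, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(geps$gep > 0))
  }
  one <- genGEPs(tinySpec(seed = 3, nEcoregions = 1))
  expect_true(all(one$gep == 1))
})

test_that("threat records carry a recoverable planted truth", {
  rec <- genThreatRecords(tinySpec(seed = 8))
  expect_true(all(c("species", "category", "threat_codes", "criteria",
                    "qualifies") %in% names(rec)))
  # an all-least-concern table qualifies nobody
  lc <- rec; lc$category <- "LC"
  expect_length(filterThreatened(lc), 0)
})

test_that("a generated world passes its validity checks end to end", {
  w <- genWorld(tinySpec(seed = 4, nEcoregions = 3))
  expect_s4_class(w, "SyntheticWorld")
  expect_length(landscapes(w), 3)
  ov <- overlapTable(w)
  eco <- ecoregionTable(w)
  perEco <- tapply(ov$area, ov$ecoregion, sum)
  expect_equal(as.vector(perEco[eco$ecoregion]), eco$area, tolerance = 1e-9)
  expect_true(all(table(ov$ecoregion) >= 1))
})

test_that("the fragmentation dial moves mean ECA/A monotonically (spot check)", {
  ratios <- vapply(c(0, 1), function(phi) {
    vals <- vapply(1:5, function(seed) {
      spec <- tinySpec(seed = seed, nEcoregions = 1, phi = phi)
      g <- genLandscape(spec, 1)
      s <- classConnectivity(g, worldLegend(spec), dMed = 2000)
      s <- s[s$land_use != "natural", ]
      mean(s$ECA / s$A)
    }, 0)
    mean(vals)
  }, 0)
  expect_lt(ratios[2], ratios[1])
})
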