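test_that("affinity from richness follows the power-law with a cap", {
  expect_equal(affinityFromRR(1, 0.3), 1)
  expect_equal(affinityFromRR(0.5, 0.25), 0.5^4)
  expect_equal(affinityFromRR(1.2, 0.25), 1)  # clamped
  expect_error(affinityFromRR(0, 0.25), "positive")
  expect_error(affinityFromRR(0.5, 1.2), "\\(0, 1\\)")
  # back-calculation inverts the un-clamped branch
  expect_equal(rrFromAffinity(affinityFromRR(0.7, 0.2), 0.2), 0.7,
               tolerance = 1e-12)
})

test_that("intensity scaling factors are richness ratios, flagged above 1", {
  expect_equal(intensityScalingFactor(0.8, 0.8), 1)
  expect_equal(intensityScalingFactor(0.6, 0.8), 0.75)
  expect_warning(f <- intensityScalingFactor(0.9, 0.6), "> 1")
  expect_equal(f, 1.5)
  expect_error(intensityScalingFactor(0.5, 0), "positive")
})

test_that("affinity rescaling acts in richness space through 1/z", {
  expect_equal(rescaleAffinity(0.4, 1, 0.25), 0.4)
  expect_equal(rescaleAffinity(0.4, 0.5, 0.25), 0.4 * 0.5^4)
  expect_equal(rescaleAffinity(0.9, 2, 0.25), 1)  # capped
  # monotone in f
  f <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(rescaleAffinity(0.5, f, 0.3)) >= 0))
})

test_that("intensity merging needs both practical and statistical support", {
  two <- data.frame(intensity = c("minimal", "light"),
                    rr = c(0.62, 0.60), se = c(0.05, 0.05))
  m <- mergeIntensityLevels(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$intensity, "minimal+light")
  # inverse-variance mean of equal-variance estimates is the plain mean
  expect_equal(m$rr, 0.61)
  # independent check of the Welch decision: p ~ 0.78 >= 0.05
  p <- 2 * pnorm(-abs((0.62 - 0.60) / sqrt(0.05^2 + 0.05^2)))
  expect_gte(p, 0.05)
  expect_equal(p, 0.7773, tolerance = 1e-3)

  far <- data.frame(intensity = c("minimal", "light"),
                    rr = c(0.9, 0.6), se = c(0.001, 0.001))
  expect_equal(nrow(mergeIntensityLevels(far)), 2)

  # statistically indistinguishable but practically distinct: |d| >= 0.05
  wide <- data.frame(intensity = c("minimal", "light"),
                     rr = c(0.9, 0.6), se = c(0.5, 0.5))
  expect_equal(nrow(mergeIntensityLevels(wide)), 2)

  three <- data.frame(intensity = c("minimal", "light", "intense"),
                      rr = c(0.62, 0.60, 0.59), se = rep(0.05, 3))
  m3 <- mergeIntensityLevels(three)
  expect_equal(nrow(m3), 1)
  # oracle: every adjacent pair merges on its own
  for (i in 1:2) {
    pair <- three[i:(i + 1), ]
    expect_equal(nrow(mergeIntensityLevels(pair)), 1)
  }
})

test_that("merge limits: zero threshold merges nothing, Inf threshold all", {
  x <- data.frame(intensity = c("minimal", "light", "intense"),
                  rr = c(0.8, 0.6, 0.3), se = rep(0.1, 3))
  expect_equal(nrow(mergeIntensityLevels(x, absThreshold = 0, alpha = 0)), 3)
  expect_equal(nrow(mergeIntensityLevels(x, absThreshold = Inf, alpha = 0)), 1)
})

test_that("missing SEs keep levels separate with a warning", {
  x <- data.frame(intensity = c("minimal", "light"),
                  rr = c(0.62, 0.60), se = c(0.05, NA))
  expect_warning(m <- mergeIntensityLevels(x), "missing standard error")
  expect_equal(nrow(m), 2)
})

test_that("plant resistance reflects the richness gradient into the matrix", {
  expect_equal(resistancePlants(0.8, 0.8), 0)
  expect_equal(resistancePlants(1.0, 0.25), 0.75)
  expect_equal(resistancePlants(0.5, 0.9), 0)  # richer matrix: clamp
  rr_k <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(resistancePlants(1, rr_k)) <= 0))
})

test_that("vertebrate resistance combines overlap and intensity scaling", {
  expect_equal(resistanceVertebrates(100, 100, 1), 0)
  expect_equal(resistanceVertebrates(100, 40, 0.75), 0.70)
  expect_equal(resistanceVertebrates(50, 0, 0.2), 1)
  expect_equal(resistanceVertebrates(100, 40, 1.5), 0.6)  # f capped at 1
  expect_error(resistanceVertebrates(10, 11, 1), "S_habitat")
})

test_that("taxonomic gap-filling walks genus -> family -> ... -> kingdom", {
  tr <- data.frame(
    species = paste0("s", 1:5),
    genus = c("Ga", "Ga", "Ga", "Gb", "Gc"),
    family = c("Fa", "Fa", "Fa", "Fa", "Fb"),
    order = "O", class = "C", kingdom = "K",
    dispersal_m = c(100, 300, NA, NA, NA),
    stringsAsFactors = FALSE)
  filled <- fillDispersalGaps(tr)
  expect_equal(filled$dispersal_m[3], 200)          # congener mean
  expect_equal(filled$fill_level[3], "genus")
  expect_equal(filled$dispersal_m[4], 200)          # family mean (100, 300)
  expect_equal(filled$fill_level[4], "family")
  expect_equal(filled$dispersal_m[5], 200)          # falls through to order
  expect_true(filled$fill_level[5] %in% c("order", "class", "kingdom"))
  expect_equal(filled$dispersal_m[1:2], c(100, 300))  # observed untouched

  # idempotence / no-op on complete tables
  again <- fillDispersalGaps(filled)
  expect_equal(again$dispersal_m, filled$dispersal_m)
  expect_true(all(again$fill_level[1:2] == "observed"))
  expect_error(fillDispersalGaps(tr[0, ]), "empty")
  tr$dispersal_m <- NA_real_
  expect_error(fillDispersalGaps(tr), "known dispersal")
})

test_that("median dispersal per ecoregion, with the amphibian constant", {
  tr <- data.frame(species = paste0("s", 1:3), group = "plants",
                   dispersal_m = c(1e3, 1e4, 1e5),
                   stringsAsFactors = FALSE)
  pres <- data.frame(species = c("s1", "s2", "s3", "s1"),
                     ecoregion = c("e1", "e1", "e1", "e2"),
                     stringsAsFactors = FALSE)
  d <- medianDispersal(tr, pres)
  expect_equal(d$d_med[d$group == "plants" & d$ecoregion == "e1"], 1e4)
  expect_equal(d$d_med[d$group == "plants" & d$ecoregion == "e2"], 1e3)

  tr2 <- rbind(tr, data.frame(species = "s9", group = "amphibians",
                              dispersal_m = 50))
  d2 <- medianDispersal(tr2, pres)
  expect_true(all(d2$d_med[d2$group == "amphibians"] == 9000))
})
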