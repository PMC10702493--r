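test_that("taxonomic aggregation is the two-step equal-weight mean", {
  v <- c(plants = 0.2, birds = 0.1, mammals = 0.2, amphibians = 0.3,
         reptiles = 0.4)
  agg <- aggregateTaxa(v)
  expect_equal(agg$value, 0.5 * (0.2 + 0.25))
  expect_equal(agg$vertebrate_mean, 0.25)
  expect_false(agg$flagged)

  # idempotence when all groups agree
  same <- setNames(rep(0.07, 5), names(v))
  expect_equal(aggregateTaxa(same)$value, 0.07)

  # equal group weights regardless of how many vertebrate groups there are
  set.seed(1)
  for (i in 1:5) {
    x <- setNames(runif(4), c("plants", "birds", "mammals", "reptiles"))
    want <- 0.5 * (x[["plants"]] + mean(x[c("birds", "mammals", "reptiles")]))
    expect_equal(aggregateTaxa(x)$value, want)
  }

  expect_warning(one <- aggregateTaxa(c(birds = 0.1, mammals = 0.3)),
                 "missing kingdom")
  expect_equal(one$value, 0.2)
  expect_true(one$flagged)
})

test_that("spatial aggregation is a convex combination with weighted SD", {
  a <- aggregateSpatial(4.2e-12, 1)
  expect_equal(a$value, 4.2e-12)
  expect_equal(a$sd, 0)

  a <- aggregateSpatial(c(1e-12, 3e-12), c(1, 3))
  expect_equal(a$value, 2.5e-12)
  expect_gt(a$rel_sd, 0)

  set.seed(3)
  for (i in 1:10) {
    cf <- runif(6); w <- runif(6)
    r <- aggregateSpatial(cf, w)
    expect_gte(r$value, min(cf))
    expect_lte(r$value, max(cf))
  }
  expect_equal(aggregateSpatial(rep(2, 4), runif(4))$sd, 0)
  expect_error(aggregateSpatial(1:2, c(0, 0)), "zero")
  expect_error(aggregateSpatial(1:2, c(-1, 2)), ">= 0")
})

test_that("intensity proxy rescales through the affinity deficit", {
  sib <- data.frame(intensity = c("minimal", "intense"),
                    value = c(2e-12, 6e-12), h = c(0.8, 0.4))
  # target = an available level: returned unchanged
  same <- proxyIntensity(sib, "intense", 0.4)
  expect_equal(same$value, 6e-12)
  # light sits between; nearest by rank is minimal (tie broken low)
  px <- proxyIntensity(sib, "light", 0.6)
  expect_equal(px$source, "minimal")
  expect_equal(px$value, 2e-12 * (1 - 0.6) / (1 - 0.8))
  # unusable siblings fall through
  harmless <- data.frame(intensity = "minimal", value = 1e-12, h = 1)
  expect_null(proxyIntensity(harmless, "light", 0.5))
})

test_that("biome proxy averages native donors and applies the GEP", {
  expect_equal(proxyBiome(c(2e-12, 4e-12), 0.01), 3e-14)
  expect_equal(proxyBiome(5e-12, 0.5), 2.5e-12)
  expect_equal(proxyBiome(c(2e-12, 4e-12)), 3e-12)  # regional form
  expect_true(is.na(proxyBiome(numeric(0), 0.1)))
})

test_that("GEP proxy uses the biome's mean density times the target area", {
  expect_equal(proxyGEP(c(1e-3, 3e-3), c(1e6, 1e6), 1e6), 2e-3)
  expect_equal(proxyGEP(0.5, 2e6, 2e6), 0.5)
  expect_true(is.na(proxyGEP(numeric(0), numeric(0), 1e6)))
})

test_that("country proxy picks the 3 nearest and pools SDs", {
  cand <- data.frame(country = paste0("c", 1:5),
                     x = c(0, 1, 2, 10, 11), y = 0,
                     value = c(1e-12, 2e-12, 3e-12, 9e-12, 9e-12),
                     sd = c(1e-13, 1e-13, 1e-13, 1e-13, 1e-13),
                     stringsAsFactors = FALSE)
  px <- proxyCountry(c(0, 0), cand)
  # brute-force nearest 3 by distance sort
  d <- sqrt(cand$x^2 + cand$y^2)
  want <- cand$country[order(d)][1:3]
  expect_setequal(px$neighbours, want)
  expect_equal(px$value, 2e-12)

  ident <- data.frame(country = paste0("c", 1:3), x = 1:3, y = 0,
                      value = 5e-12, sd = 2e-13, stringsAsFactors = FALSE)
  pi2 <- proxyCountry(c(0, 0), ident)
  expect_equal(pi2$value, 5e-12)
  expect_equal(pi2$sd, 2e-13)  # no between-mean spread

  expect_warning(few <- proxyCountry(c(0, 0), ident[1:2, ]), "fewer than")
  expect_equal(few$value, 5e-12)
  expect_error(proxyCountry(c(0, 0), ident[0, ]), "no candidate")
})
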