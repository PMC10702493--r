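simpleLegend <- makeLegend(0:2, c("natural", "cropland", "cropland"),
                           c("natural", "minimal", "intense"))

test_that("patch extraction partitions class cells by connectivity rule", {
  m <- matrix(0L, 3, 3); m[] <- 1L
  g <- landscapeGrid(m, 100, "e")
  p <- extractPatches(g, simpleLegend, "cropland", "minimal")
  expect_length(p, 1)
  expect_equal(p[[1]]$area, 9 * 100^2)

  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal cells
  g <- landscapeGrid(m, 100, "e")
  expect_length(extractPatches(g, simpleLegend, "cropland", "minimal", 4), 2)
  expect_length(extractPatches(g, simpleLegend, "cropland", "minimal", 8), 1)

  expect_error(extractPatches(g, simpleLegend, "mine", "minimal"),
               "not in legend")
  expect_identical(extractPatches(g, simpleLegend, "cropland", "intense"),
                   list())
})

test_that("patch labelling matches a flood-fill oracle on random grids", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(sample(0:2, 400, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                20, 20)
    g <- landscapeGrid(m, 50, "e")
    for (conn in c(4, 8)) {
      got <- extractPatches(g, simpleLegend, "cropland", "minimal", conn)
      gotSets <- lapply(got, function(p) {
        sort(p$cells[, "row"] + (p$cells[, "col"] - 1) * nrow(m))
      })
      want <- oracleFloodFill(m, 1L, conn)
      expect_equal(length(gotSets), length(want))
      expect_setequal(vapply(gotSets, paste, "", collapse = ","),
                      vapply(want, paste, "", collapse = ","))
    }
  }
})

test_that("patch distances: adjacency, r = 0 limit, and barrier cost", {
  m <- matrix(0L, 5, 5)
  m[, 1] <- 1L; m[, 2] <- 2L  # touching columns, different classes
  g <- landscapeGrid(m, 100, "e")
  a <- extractPatches(g, simpleLegend, "cropland", "minimal")[[1]]
  b <- extractPatches(g, simpleLegend, "cropland", "intense")[[1]]
  expect_equal(patchDistance(a, b, g), 100)  # one cell step

  # all-zero resistance: least-cost equals the straight grid-metric path
  m <- matrix(0L, 5, 7); m[3, 1] <- 1L; m[3, 7] <- 2L
  g <- landscapeGrid(m, 100, "e")
  a <- extractPatches(g, simpleLegend, "cropland", "minimal")[[1]]
  b <- extractPatches(g, simpleLegend, "cropland", "intense")[[1]]
  r0 <- matrix(0, 5, 7)
  expect_equal(patchDistance(a, b, g, r0), patchDistance(a, b, g))

  # high-resistance barrier row: least-cost >= Euclidean, equals Dijkstra
  rbar <- matrix(0, 5, 7); rbar[, 4] <- 1
  dBar <- patchDistance(a, b, g, rbar)
  expect_gte(dBar, patchDistance(a, b, g))
  want <- oracleLeastCost(rbar, 100,
                          a$cells[, 1] + (a$cells[, 2] - 1) * 5,
                          b$cells[, 1] + (b$cells[, 2] - 1) * 5)
  expect_equal(dBar, want, tolerance = 1e-12)

  expect_error(patchDistance(a, a, g), "overlap")
})

test_that("raising resistance never shortens effective distances", {
  set.seed(42)
  m <- matrix(0L, 8, 8); m[2, 2] <- 1L; m[7, 7] <- 1L; m[2, 7] <- 1L
  g <- landscapeGrid(m, 100, "e")
  p <- extractPatches(g, simpleLegend, "cropland", "minimal")
  r1 <- matrix(runif(64, 0, 0.5), 8, 8)
  r2 <- r1 + matrix(runif(64, 0, 0.5), 8, 8)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(patchDistance(p[[i]], p[[j]], g, r2),
               patchDistance(p[[i]], p[[j]], g, r1) - 1e-9)
  }
})

test_that("dispersal kernel honours the median-distance contract", {
  expect_equal(dispersalProbability(0, 5000), 1)
  expect_equal(dispersalProbability(5000, 5000), 0.5)
  expect_equal(dispersalProbability(10000, 5000), 0.25)
  d <- seq(0, 1e5, by = 1000)
  expect_true(all(diff(dispersalProbability(d, 9000)) < 0))
  expect_error(dispersalProbability(-1, 5000), ">= 0")
  expect_error(dispersalProbability(10, -5), "positive")
})

test_that("ECA closed forms and oracle equivalence", {
  expect_equal(equivalentConnectedArea(5, matrix(1, 1, 1)), 5)
  A <- 1e6
  expect_equal(equivalentConnectedArea(c(A, A), matrix(1, 2, 2)), 2 * A)
  expect_equal(equivalentConnectedArea(c(A, A), diag(2)), A * sqrt(2))
  set.seed(7)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    areas <- runif(n, 1e4, 1e7)
    p <- randomProbMatrix(n)
    expect_equal(equivalentConnectedArea(areas, p), oracleECA(areas, p),
                 tolerance = 1e-13)
  }
  expect_error(equivalentConnectedArea(c(1, 2), matrix(1, 3, 3)), "match")
})

test_that("ECA bounds and monotonicity invariants", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    areas <- runif(n, 1e4, 1e7)
    p <- randomProbMatrix(n)
    eca <- equivalentConnectedArea(areas, p)
    expect_gte(eca, max(areas))
    expect_lte(eca, sum(areas) * (1 + 1e-12))
    # monotone in p
    p2 <- p
    i1 <- sample(n, 1); i2 <- sample(setdiff(seq_len(n), i1), 1)
    p2[i1, i2] <- p2[i2, i1] <- min(1, p[i1, i2] + 0.1)
    expect_gte(equivalentConnectedArea(areas, p2), eca)
    # monotone in A
    a2 <- areas; a2[i1] <- a2[i1] * 1.2
    expect_gte(equivalentConnectedArea(a2, p), eca)
  }
  # splitting a patch with imperfect connection strictly decreases ECA
  whole <- equivalentConnectedArea(2e6, matrix(1, 1, 1))
  p <- matrix(c(1, 0.8, 0.8, 1), 2)
  split <- equivalentConnectedArea(c(1e6, 1e6), p)
  expect_lt(split, whole)
})

test_that("class connectivity summary covers present classes with ECA <= A", {
  m <- matrix(0L, 6, 6)
  g <- landscapeGrid(m, 1000, "e")
  s <- classConnectivity(g, simpleLegend, dMed = 2000)
  expect_equal(nrow(s), 1)
  expect_equal(s$land_use, "natural")
  expect_equal(s$ECA, s$A)
  expect_equal(s$A, 36 * 1000^2)

  m[2:4, 2:4] <- 1L  # one solid block
  g <- landscapeGrid(m, 1000, "e")
  s <- classConnectivity(g, simpleLegend, dMed = 2000)
  blk <- s[s$land_use == "cropland", ]
  expect_equal(blk$ECA, blk$A)
  expect_true(all(s$ECA <= s$A + 1e-9))
})

test_that("spreading a class over more patches lowers its ECA", {
  legend <- simpleLegend
  ecaOf <- function(cells) {
    m <- matrix(0L, 12, 12)
    m[cells] <- 1L
    g <- landscapeGrid(m, 1000, "e")
    s <- classConnectivity(g, legend, dMed = 1500)
    s$ECA[s$land_use == "cropland"]
  }
  one <- ecaOf(cbind(rep(1:2, each = 4), rep(1:4, 2)))          # 2x4 block
  two <- ecaOf(rbind(cbind(rep(1:2, each = 2), rep(1:2, 2)),
                     cbind(rep(11:12, each = 2), rep(11:12, 2)))) # 2 blocks
  four <- ecaOf(cbind(c(1, 1, 12, 12, 6, 6, 1, 12),
                      c(1, 12, 1, 12, 1, 12, 6, 6)))             # scattered
  expect_lt(two, one)
  expect_lt(four, two)
})
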