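test_that("the factorial design enumerates all study combinations", {
  d <- factorialDesign()
  expect_identical(nrow(d), 1100L)
  expect_identical(sum(d$L > 1), 1080L)
  expect_identical(sum(d$L == 1), 20L)
  big <- d[d$L > 1, ]
  expect_false(anyDuplicated(big[, c("K", "L", "R", "h", "c",
                                     "freqModel")]) > 0)
  expect_setequal(unique(d$K), c(1, 2, 5, 10, 20))
  expect_setequal(unique(big$R), c(1, 25, 50))
  expect_true(all(d$chromLength == 240e6 & d$rate == 1.2))
})

test_that("design maps span R centimorgans symmetrically", {
  m <- makeDesignMap(10, 50)
  expect_equal(diff(range(mapPositions(m))), 50 / 1.2 * 1e6)  # 41.667 Mb
  expect_equal(unique(round(diff(mapPositions(m)))),
               round(50 / 1.2 * 1e6 / 9))
  expect_equal(sum(mapLengths(m)) * 100, 50, tolerance = 1e-9)
  expect_equal(mean(range(mapPositions(m))), 120e6)  # centered
  m1 <- makeDesignMap(1, 50)
  expect_identical(nMarkers(m1), 1L)
  expect_error(makeDesignMap(10, 5000), "exceeds")
})

test_that("switching-process panels are distinct with the requested flip rate", {
  set.seed(61)
  expect_error(simulateHaplotypePanel(5, 2), "distinct")
  # c = 0: only constant haplotypes exist
  constant <- simulateHaplotypePanel(2, 6, c = 0)
  expect_setequal(constant, c(0L, 63L))
  panel <- simulateHaplotypePanel(15, 10, c = 1)
  expect_identical(length(unique(panel)), 15L)
  # empirical flip frequency across intervals ~ p = c/L
  draws <- replicate(3000, simulateHaplotypePanel(1, 10, c = 1))
  bits <- t(vapply(draws, hapToBits, integer(10), L = 10))
  flips <- abs(bits[, -1] - bits[, -10])
  phat <- mean(flips)
  se <- sqrt(0.1 * 0.9 / length(flips))
  expect_lt(abs(phat - 0.1), 4 * se)
  # and the first allele is fair
  expect_lt(abs(mean(bits[, 1]) - 0.5), 4 * sqrt(0.25 / nrow(bits)))
})

test_that("Dirichlet frequency draws have the designed means", {
  set.seed(71)
  sym <- replicate(4000, simulateFrequencies(5, "alpha1"))
  expect_lt(max(abs(rowMeans(sym) - 0.2)), 0.02)
  nonsym <- replicate(4000, simulateFrequencies(5, "w20"))
  expect_lt(abs(mean(nonsym[1, ]) - 0.7), 0.02)
  expect_lt(max(abs(rowMeans(nonsym)[-1] - 0.075)), 0.02)
  # h = 2 reduces to the Beta settings of the single-locus design
  beta <- replicate(4000, simulateFrequencies(2, "w5")[1])
  expect_lt(abs(mean(beta) - 0.7), 0.03)
  expect_error(simulateFrequencies(1, "alpha1"), "at least 2")
  expect_error(simulateFrequencies(5, "banana"))
})

test_that("recombinant gametes reproduce the ancestry-state distribution", {
  set.seed(81)
  map <- mapFromMorgans(c(0.15, 0.4))
  # identical parents: gamete equals both, whatever the crossovers
  expect_identical(simulateRecombinantGametes(5L, 5L, map, n = 20),
                   rep(5L, 20))
  # zero map length: gamete is one whole parent
  tight <- MarkerMap("c", c(1e6, 1e6 + 1, 1e6 + 2), rates = 1e-9)
  g <- simulateRecombinantGametes(0L, 7L, tight, n = 400)
  expect_true(all(g %in% c(0L, 7L)))
  expect_gt(mean(g == 0L), 0.35)  # founder fair coin
  # ancestry states: simulate with distinguishable parents (A = 000, B = 111)
  n <- 40000
  z <- simulateRecombinantGametes(0L, 7L, map, n = n)
  emp <- tabulate(z + 1L, nbins = 8) / n
  q <- ancestryStatePriors(map)
  se <- sqrt(pmax(q * (1 - q), 1e-12) / n)
  expect_true(all(abs(emp - q) < 4 * se + 1e-3))
  expect_error(simulateRecombinantGametes(9L, 0L, map, n = 1), "exceed")
})

test_that("per-class diplotypes follow the pedigree recipes", {
  set.seed(91)
  map <- mapFromMorgans(c(0.1, 0.1))
  # population A fixed for 000, B fixed for 111
  tab <- HaplotypeFreqTable("c", 3, c(0L, 7L), c(1, 0), c(0, 1))
  expect_identical(simulateIndividual("d", tab, map)@hapM, 0L)
  expect_identical(simulateIndividual("a", tab, map)@hapP, 7L)
  f1 <- simulateIndividual("c", tab, map)
  expect_setequal(c(f1@hapM, f1@hapP), c(0L, 7L))
  # backcross with A: one pure-A copy and one mosaic
  bc <- simulateIndividual("b", tab, map)
  expect_identical(bc@hapM, 0L)
  # Hardy-Weinberg of class-a genotypes at a single marker
  t1 <- singleMarkerTable(0.2, 0.7)
  m1 <- MarkerMap("c", 1e6, rates = 1.2)
  hap <- replicate(20000, {
    ind <- simulateIndividual("a", t1, m1); ind@hapM + ind@hapP
  })
  freq <- tabulate(hap + 1L, nbins = 3) / 20000
  hw <- c(0.3^2, 2 * 0.3 * 0.7, 0.7^2)
  expect_true(all(abs(freq - hw) < 4 * sqrt(hw * (1 - hw) / 20000)))
})

test_that("pool composition mirrors the class recipes", {
  set.seed(101)
  map <- mapFromMorgans(c(0.1, 0.2))
  poolA <- c(0L, 1L); poolB <- c(6L, 7L)
  d <- composeFromPools(poolA, poolB, "d", map)
  expect_true(all(c(d@hapM, d@hapP) %in% poolA))
  # parents drawn without replacement: the two copies differ
  expect_false(any(d@hapM == d@hapP))
  f <- composeFromPools(poolA, poolB, "f", map)
  # F2 copies are mosaics of one A-pool and one B-pool haplotype: with
  # these pools, marker 1 of each copy comes from {0,1} x {6,7} bit 0
  expect_true(all(c(f@hapM, f@hapP) >= 0 & c(f@hapM, f@hapP) <= 7))
  expect_error(composeFromPools(0L, poolB, "d", map), "at least 2")
})

test_that("simulation is reproducible under a fixed seed", {
  run <- function() {
    set.seed(123)
    simulateDataset(n = 25, K = 2, L = 5, R = 25, h = 5, c = 0.1)
  }
  a <- run(); b <- run()
  expect_identical(a$hapM, b$hapM)
  expect_identical(a$hapP, b$hapP)
  expect_identical(a$classes, b$classes)
})
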