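test_that("haplotype probability given an ancestry state multiplies segment marginals", {
  set.seed(5)
  tab <- randomTable(3)
  fA <- popFrequencies(tab, "A"); fB <- popFrequencies(tab, "B")
  # trivial cases: all-A and all-B states give the full-haplotype frequency
  for (x in 0:7) {
    expect_equal(seqProbGivenState(x, 0L, tab), fA[x + 1])
    expect_equal(seqProbGivenState(x, 7L, tab), fB[x + 1])
  }
  # two-segment case z = (0,0,1): f^A(x[1,2]) * f^B(x[3,3])
  x <- stringToHap("101")
  byHand <- marginalFrequency(tab, "A", 1, 2, stringToHap("10")) *
    marginalFrequency(tab, "B", 3, 3, 1L)
  expect_equal(seqProbGivenState(x, stringToHap("001"), tab), byHand,
               tolerance = 1e-12)
  # normalization over haplotypes for every state
  for (z in 0:7) {
    tot <- sum(sapply(0:7, function(x) seqProbGivenState(x, z, tab)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # independent oracle across random states
  sup <- allBitVectors(3)
  for (x in 0:7) for (z in c(1L, 3L, 5L)) {
    expect_equal(seqProbGivenState(x, z, tab),
                 oracleSeqProb(hapToBits(x, 3), hapToBits(z, 3), sup, fA,
                               fB),
                 tolerance = 1e-12)
  }
})

test_that("recombinant likelihood equals the state-sum oracle and normalizes", {
  set.seed(9)
  for (L in c(1, 2, 4)) {
    tab <- randomTable(L)
    mor <- runif(max(L - 1, 1), 0.01, 0.5)[seq_len(L - 1)]
    map <- if (L == 1) MarkerMap("chr1", 1e6, rates = 2) else
      mapFromMorgans(mor)
    rl <- recombinantLikelihoods(0:(2^L - 1), map, tab)
    expect_equal(sum(rl), 1, tolerance = 1e-12)
    sup <- allBitVectors(L)
    fA <- popFrequencies(tab, "A"); fB <- popFrequencies(tab, "B")
    P <- probStateChange(mapLengths(map))
    oracle <- sapply(0:(2^L - 1), function(x)
      oracleRecombLik(hapToBits(x, L), P, sup, fA, fB))
    expect_equal(rl, oracle, tolerance = 1e-12)
  }
})

test_that("recombinant likelihood collapses to the pure mixture without recombination", {
  set.seed(13)
  tab <- randomTable(3)
  fA <- popFrequencies(tab, "A"); fB <- popFrequencies(tab, "B")
  tight <- MarkerMap("chr1", c(1e6, 1e6 + 1, 1e6 + 2), rates = 1e-9)
  rl <- recombinantLikelihoods(0:7, tight, tab)
  expect_equal(rl, (fA + fB) / 2, tolerance = 1e-9)
  # L = 1 always gives the pure mixture
  t1 <- singleMarkerTable(0.3, 0.8)
  m1 <- MarkerMap("chr1", 5e6, rates = 100)
  expect_equal(recombinantLikelihood(1L, m1, t1), (0.3 + 0.8) / 2)
  expect_error(recombinantLikelihoods(0:7, mapFromMorgans(rep(0.1, 11)),
                                      randomTable(2)), "disagree")
})

test_that("class likelihoods reproduce hand-computed single-marker values", {
  # f^A = {h1: 0.7, h2: 0.3}, f^B = {h1: 0.2, h2: 0.8}; dip = (h1, h2)
  tab <- HaplotypeFreqTable("c", 1, c(0L, 1L), c(0.7, 0.3), c(0.2, 0.8))
  map <- MarkerMap("c", 1e6, rates = 2)
  dip <- Diplotype(0L, 1L)
  expect_equal(exp(classLikelihood(dip, "c", map, tab)),
               0.7 * 0.8 + 0.3 * 0.2)              # 0.62
  expect_equal(exp(classLikelihood(dip, "a", map, tab)), 2 * 0.2 * 0.8)
  expect_equal(exp(classLikelihood(dip, "d", map, tab)), 2 * 0.7 * 0.3)
  # recombinant copies at L = 1 carry frequency (fA + fB)/2
  q0 <- (0.7 + 0.2) / 2; q1 <- (0.3 + 0.8) / 2
  expect_equal(exp(classLikelihood(dip, "b", map, tab)),
               0.7 * q1 + 0.3 * q0)
  expect_equal(exp(classLikelihood(dip, "e", map, tab)),
               0.2 * q1 + 0.8 * q0)
  expect_equal(exp(classLikelihood(dip, "f", map, tab)), 2 * q0 * q1)
})

test_that("class likelihoods are symmetric and normalized over diplotypes", {
  set.seed(21)
  tab <- randomTable(3)
  map <- mapFromMorgans(c(0.15, 0.4))
  haps <- 0:7
  # exhaustive normalization: sum over unordered diplotypes of each class
  for (g in labels6) {
    tot <- 0
    for (i in haps) for (j in haps[haps >= i]) {
      tot <- tot + exp(classLikelihood(Diplotype(i, j), g, map, tab))
    }
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  # maternal/paternal label swap leaves every class unchanged
  for (g in labels6) {
    expect_equal(classLikelihood(Diplotype(2L, 5L), g, map, tab),
                 classLikelihood(Diplotype(5L, 2L), g, map, tab))
  }
  # population swap maps a<->d, b<->e, keeps c and f
  swapped <- HaplotypeFreqTable("c", 3, supportHaps(tab),
                                popFrequencies(tab, "B"),
                                popFrequencies(tab, "A"))
  dip <- Diplotype(3L, 6L)
  pairs <- list(c("a", "d"), c("b", "e"), c("c", "c"), c("f", "f"))
  for (p in pairs) {
    expect_equal(classLikelihood(dip, p[1], map, tab),
                 classLikelihood(dip, p[2], map, swapped),
                 tolerance = 1e-12)
  }
})

test_that("posteriors follow Bayes' rule and handle degenerate priors", {
  tab <- singleMarkerTable(0.5, 0.5)  # indistinguishable populations
  map <- MarkerMap("c", 1e6, rates = 2)
  p <- posteriorOverClasses(Diplotype(0L, 1L), map, tab)
  expect_equal(unname(posteriorProbs(p)), rep(1 / 6, 6), tolerance = 1e-12)
  prior <- c(0, 0, 1, 0, 0, 0)
  p2 <- posteriorOverClasses(Diplotype(0L, 1L), map, tab, prior = prior)
  expect_equal(unname(posteriorProbs(p2)), prior)
  expect_error(posteriorOverClasses(Diplotype(0L, 1L), map, tab,
                                    prior = rep(0.2, 6)), "prior")
  # hand-normalized six likelihoods
  tab2 <- HaplotypeFreqTable("c", 1, c(0L, 1L), c(0.7, 0.3), c(0.2, 0.8))
  lik <- sapply(labels6, function(g)
    exp(classLikelihood(Diplotype(0L, 1L), g, map, tab2)))
  p3 <- posteriorOverClasses(Diplotype(0L, 1L), map, tab2)
  expect_equal(unname(posteriorProbs(p3)), unname(lik / sum(lik)),
               tolerance = 1e-12)
  expect_equal(mapClass(p3), names(which.max(lik)))
})

test_that("posterior remains finite and normalized for many weak chromosomes", {
  # per-chromosome likelihoods around 1e-30: K = 20 must stay stable
  set.seed(2)
  L <- 10
  sup <- c(0L, 1023L)
  tab <- HaplotypeFreqTable("c", L, sup, c(1 - 1e-30, 1e-30),
                            c(1e-30, 1 - 1e-30))
  map <- makeDesignMap(L, 50)
  dip <- Diplotype(rep(1023L, 20), rep(0L, 20))
  p <- posteriorOverClasses(dip, rep(list(map), 20), rep(list(tab), 20))
  expect_true(all(is.finite(posteriorProbs(p))))
  expect_equal(sum(posteriorProbs(p)), 1, tolerance = 1e-12)
  expect_equal(mapClass(p), "c")
})

test_that("compatible diplotypes enumerate phase resolutions exactly once", {
  # no heterozygous site: a single diplotype
  one <- enumerateCompatibleDiplotypes(c(0L, 2L, 0L))
  expect_identical(nrow(one), 1L)
  expect_identical(unname(one[1, ]), c(2L, 2L))
  # two het sites: 2 unordered pairs
  two <- enumerateCompatibleDiplotypes(c(1L, 1L))
  expect_identical(nrow(two), 2L)
  key <- apply(two, 1, function(r) paste(sort(r), collapse = "/"))
  expect_setequal(key, c("0/3", "1/2"))
  # k het sites: 2^(k-1) pairs, all reproducing the genotype, none repeated
  for (codes in list(c(1L, 1L, 1L, 1L), c(1L, 0L, 1L, 2L, 1L, 1L))) {
    k <- sum(codes == 1L)
    prs <- enumerateCompatibleDiplotypes(codes)
    expect_equal(nrow(prs), 2^(k - 1))
    L <- length(codes)
    sums <- t(apply(prs, 1, function(r)
      hapToBits(r[1], L) + hapToBits(r[2], L)))
    expect_true(all(apply(sums, 1, function(s) all(s == codes))))
    key <- apply(prs, 1, function(r) paste(sort(r), collapse = "/"))
    expect_false(anyDuplicated(key) > 0)
  }
  expect_error(enumerateCompatibleDiplotypes(c(0L, 3L)), "0, 1 or 2")
})

test_that("unphased likelihood marginalizes phase per chromosome", {
  set.seed(31)
  tab <- randomTable(3)
  map <- mapFromMorgans(c(0.2, 0.3))
  # homozygous genotype: equals the phased likelihood of its diplotype
  gt <- Genotype(list(c(2L, 0L, 2L)))
  dip <- Diplotype(5L, 5L)
  for (g in labels6) {
    expect_equal(unphasedClassLikelihood(gt, g, map, tab),
                 classLikelihood(dip, g, map, tab), tolerance = 1e-12)
  }
  # two het sites: explicit two-term sum
  gt2 <- Genotype(list(c(1L, 0L, 1L)))
  for (g in labels6) {
    manual <- exp(classLikelihood(Diplotype(0L, 5L), g, map, tab)) +
      exp(classLikelihood(Diplotype(1L, 4L), g, map, tab))
    expect_equal(exp(unphasedClassLikelihood(gt2, g, map, tab)), manual,
                 tolerance = 1e-12)
  }
  # posteriors over classes normalize
  pp <- posteriorOverClasses(Genotype(list(c(1L, 1L, 0L))), map, tab)
  expect_equal(sum(posteriorProbs(pp)), 1, tolerance = 1e-12)
})

test_that("batch classification matches the single-individual path", {
  set.seed(41)
  sim <- simulateDataset(n = 40, K = 3, L = 5, R = 25, h = 5, c = 0.1)
  out <- classifyIndividuals(sim$hapM, sim$hapP, sim$maps, sim$tables)
  post <- as.matrix(out[, paste0("P_", labels6)])
  expect_equal(unname(rowSums(post)), rep(1, 40), tolerance = 1e-9)
  for (i in c(1L, 17L, 40L)) {
    single <- suppressWarnings(
      posteriorOverClasses(Diplotype(sim$hapM[i, ], sim$hapP[i, ]),
                           sim$maps, sim$tables))
    expect_equal(unname(post[i, ]), unname(posteriorProbs(single)),
                 tolerance = 1e-10)
  }
})
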