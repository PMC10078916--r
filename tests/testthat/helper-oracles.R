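# Independent brute-force oracles and small fixtures. The oracles avoid the
# package's bit-mask dynamic programming entirely: they work on explicit 0/1
# vectors and enumerate paths/states directly.

labels6 <- c("a", "b", "c", "d", "e", "f")

# All 0/1 vectors of length L, one per row, ascending as binary numbers
# (marker 1 = least significant).
allBitVectors <- function(L) {
  m <- as.matrix(expand.grid(rep(list(0:1), L)))
  colnames(m) <- NULL
  m
}

# Oracle for Q(z | d, r): multiply per-interval change/no-change
# probabilities path by path, mixing over the two founder origins.
oracleStatePrior <- function(zbits, changeProbs) {
  L <- length(zbits)
  stopifnot(length(changeProbs) == L - 1)
  total <- 0
  for (founder in 0:1) {
    p <- 0.5
    prev <- founder
    for (j in seq_len(L)) {
      pc <- if (j == 1) 0 else changeProbs[j - 1]  # founder sets marker 1
      p <- p * if (zbits[j] == prev) (1 - pc) else pc
      prev <- zbits[j]
    }
    total <- total + p
  }
  total
}

# Oracle for f(x | z): walk the markers, multiply in a segment marginal
# every time the ancestry switches. freqs: data.frame-free representation,
# support as 0/1 matrix plus per-population frequency vectors.
oracleSeqProb <- function(xbits, zbits, supportBits, fA, fB) {
  L <- length(xbits)
  segs <- split(seq_len(L), cumsum(c(1, diff(zbits) != 0)))
  p <- 1
  for (seg in segs) {
    f <- if (zbits[seg[1]] == 0) fA else fB
    match <- apply(supportBits[, seg, drop = FALSE], 1, function(h)
      all(h == xbits[seg]))
    p <- p * sum(f[match])
  }
  p
}

# Oracle for the recombinant-haplotype likelihood: naive double loop over
# all 2^L ancestry states without bit tricks.
oracleRecombLik <- function(xbits, changeProbs, supportBits, fA, fB) {
  L <- length(xbits)
  states <- allBitVectors(L)
  tot <- 0
  for (r in seq_len(nrow(states))) {
    z <- states[r, ]
    tot <- tot + oracleSeqProb(xbits, z, supportBits, fA, fB) *
      oracleStatePrior(z, changeProbs)
  }
  tot
}

# Random map with L markers and given per-interval map lengths (Morgans).
mapFromMorgans <- function(mor, rate = 2, chrom = "chr1") {
  dMb <- mor * 100 / rate
  pos <- cumsum(c(1, dMb)) * 1e6
  MarkerMap(chrom, pos, rates = rate)
}

# Small random frequency table over the full 2^L support.
randomTable <- function(L, seed = NULL, chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  H <- 2^L
  fA <- rgamma(H, 1); fA <- fA / sum(fA)
  fB <- rgamma(H, 1); fB <- fB / sum(fB)
  HaplotypeFreqTable(chrom, L, 0:(H - 1L), fA, fB)
}

# Two-haplotype single-marker table (allele frequencies pA, pB for allele 1).
singleMarkerTable <- function(pA, pB, chrom = "chr1") {
  HaplotypeFreqTable(chrom, 1L, c(0L, 1L), c(1 - pA, pA), c(1 - pB, pB))
}

# Draw k haplotypes from one population of a table (test-side sampler,
# independent of the package's internals).
sampleHapsForTest <- function(table, population, k) {
  sup <- supportHaps(table)
  sup[sample.int(length(sup), k, replace = TRUE,
                 prob = popFrequencies(table, population))]
}
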