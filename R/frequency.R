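#' Build the shared haplotype support
#'
#' The set of distinct haplotypes over which both populations' frequencies
#' are defined: the union of the haplotypes seen in the two reference
#' panels, any extra haplotypes supplied directly, and every haplotype
#' compatible with the genotypes of test individuals (both phase resolutions
#' of each heterozygous configuration), in ascending bit-mask order.
#'
#' @param panelA,panelB integer haplotype bit-masks observed in the two
#'   reference panels (one entry per chromosome copy).
#' @param extra optional additional haplotype bit-masks.
#' @param genotypes optional list of genotype code vectors ({0,1,2}) from
#'   test individuals whose compatible haplotypes should be representable.
#' @param L number of markers (required when `genotypes` is given).
#' @return sorted integer vector of distinct haplotype bit-masks.
#' @examples
#' buildSupport(c(0L, 1L), c(0L, 3L))
#' @export
buildSupport <- function(panelA, panelB, extra = integer(0),
                         genotypes = NULL, L = NULL) {
  if (length(panelA) == 0L || length(panelB) == 0L) {
    stop("both reference panels must contain at least one haplotype")
  }
  haps <- c(as.integer(panelA), as.integer(panelB), as.integer(extra))
  if (any(haps < 0L)) stop("haplotype bit-masks must be >= 0")
  if (!is.null(genotypes)) {
    if (is.null(L)) stop("L is required when genotypes are supplied")
    for (g in genotypes) {
      if (length(g) != L) stop("genotype length does not match L")
      pairs <- enumerateCompatibleDiplotypes(g)
      haps <- c(haps, pairs[, 1L], pairs[, 2L])
    }
  }
  sort(unique(haps))
}

#' Dirichlet-multinomial posterior-mean haplotype frequencies
#'
#' With a symmetric Dirichlet(1/H) prior over the H support haplotypes and a
#' multinomial sample of 2N observed copies, the posterior mean frequency of
#' haplotype h is (n_h + 1/H) / (1 + 2N). The pseudocount keeps every
#' support haplotype at strictly positive frequency.
#'
#' @param counts observed copy counts per support haplotype (sums to 2N).
#' @param H support size (defaults to `length(counts)`).
#' @param N diploid panel size (defaults to `sum(counts) / 2`).
#' @return frequencies, strictly positive, summing to 1.
#' @examples
#' estimateFrequencies(c(3, 1))  # (0.7, 0.3)
#' @export
estimateFrequencies <- function(counts, H = length(counts),
                                N = sum(counts) / 2) {
  if (H < 1L) stop("support size H must be at least 1")
  if (length(counts) != H) stop("need one count per support haplotype")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (abs(sum(counts) - 2 * N) > 1e-9) {
    stop("counts must sum to 2N (", 2 * N, "), got ", sum(counts))
  }
  (counts + 1 / H) / (1 + 2 * N)
}

#' Estimate a HaplotypeFreqTable from two phased reference panels
#'
#' Builds the shared support from the panels (plus any test-individual
#' genotypes), counts observed copies per population, and applies the
#' Dirichlet-multinomial posterior mean to each population separately.
#'
#' @inheritParams buildSupport
#' @param chrom chromosome identifier.
#' @param L number of markers.
#' @return A [HaplotypeFreqTable-class] with strictly positive frequencies.
#' @examples
#' estimateFreqTable(c(0L, 0L, 1L, 1L), c(3L, 3L, 3L, 1L), chrom = "chr1", L = 2)
#' @export
estimateFreqTable <- function(panelA, panelB, chrom, L,
                              extra = integer(0), genotypes = NULL) {
  support <- buildSupport(panelA, panelB, extra = extra,
                          genotypes = genotypes, L = L)
  if (any(c(panelA, panelB, extra) > 2^L - 1)) {
    stop("panel haplotypes exceed the ", L, "-marker range")
  }
  H <- length(support)
  cA <- tabulate(match(as.integer(panelA), support), nbins = H)
  cB <- tabulate(match(as.integer(panelB), support), nbins = H)
  nA <- length(panelA) / 2
  nB <- length(panelB) / 2
  HaplotypeFreqTable(chrom = chrom, nMarkers = L, support = support,
                     freqA = estimateFrequencies(cA, H = H, N = nA),
                     freqB = estimateFrequencies(cB, H = H, N = nB),
                     countA = cA, countB = cB, sizeA = nA, sizeB = nB)
}

#' Marginal frequency of a sub-haplotype
#'
#' Frequency of the allele pattern `subhap` on markers u..v in one
#' population: the sum of full-haplotype frequencies whose restriction to
#' [u, v] matches the pattern.
#'
#' @param table a [HaplotypeFreqTable-class].
#' @param population `"A"` or `"B"`.
#' @param u,v marker range, 1 <= u <= v <= L.
#' @param subhap pattern on [u, v]: integer bit-mask with marker u in bit 0,
#'   or a 0/1 vector of length v - u + 1.
#' @return probability in [0, 1].
#' @export
marginalFrequency <- function(table, population = c("A", "B"), u, v, subhap) {
  population <- match.arg(population)
  L <- nMarkers(table)
  if (u < 1L || v > L || u > v) stop("marker range [", u, ", ", v,
                                     "] out of 1..", L)
  w <- v - u + 1L
  sub <- asBitmask(subhap, w)
  f <- popFrequencies(table, population)
  mask <- bitwShiftL(2L^w - 1L, u - 1L)
  pat <- bitwShiftL(sub, u - 1L)
  sum(f[bitwAnd(table@support, mask) == pat])
}

#' Per-marker allele frequencies from a haplotype table
#'
#' Single-site marginals of the haplotype frequency table: the frequency of
#' allele 1 at each marker in each population. This is the information set
#' of the unlinked composite-likelihood baseline. Frequencies are floored
#' into (0, 1) so that no genotype has probability exactly zero under any
#' class.
#'
#' @param table a [HaplotypeFreqTable-class].
#' @param floor lower bound applied symmetrically (default 1e-12).
#' @return data.frame with columns `marker`, `pA`, `pB`.
#' @export
alleleFrequencies <- function(table, floor = 1e-12) {
  L <- nMarkers(table)
  pA <- vapply(seq_len(L), function(j)
    marginalFrequency(table, "A", j, j, 1L), numeric(1))
  pB <- vapply(seq_len(L), function(j)
    marginalFrequency(table, "B", j, j, 1L), numeric(1))
  data.frame(marker = seq_len(L),
             pA = pmin(pmax(pA, floor), 1 - floor),
             pB = pmin(pmax(pB, floor), 1 - floor))
}
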