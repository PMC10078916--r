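#' @useDynLib hybridclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is
#' @importFrom stats rbinom rgamma runif setNames
#' @importFrom utils read.delim write.table
NULL

CLASS_LABELS <- c("a", "b", "c", "d", "e", "f")

#' MarkerMap: marker positions and recombination rates on one chromosome
#'
#' Holds the physical positions (bp) of L biallelic SNP markers on a
#' chromosome together with a recombination rate (cM/Mb) for each interval.
#' The rate on element j applies to the interval ending at marker j; element
#' 1 covers the interval from the 5' end of the chromosome to marker 1 and
#' has no effect on any ancestry-state probability (the founder-origin
#' mixture makes the first interval drop out), but is retained so that maps
#' round-trip through files unchanged.
#'
#' @slot chrom chromosome (or scaffold) identifier.
#' @slot positions strictly increasing marker positions in base pairs.
#' @slot rates per-interval recombination rates in cM/Mb, one per marker.
#' @export
setClass("MarkerMap", representation(
  chrom = "character",
  positions = "numeric",
  rates = "numeric"
))

setValidity("MarkerMap", function(object) {
  p <- object@positions
  r <- object@rates
  if (length(object@chrom) != 1L) return("chrom must be a single identifier")
  if (length(p) < 1L) return("at least one marker is required")
  if (any(!is.finite(p))) return("positions must be finite")
  if (length(p) > 1L && any(diff(p) <= 0)) {
    return("positions must be strictly increasing")
  }
  if (length(r) != length(p)) {
    return("need one rate per marker (5' interval plus L-1 internal intervals)")
  }
  if (any(!is.finite(r)) || any(r < 0)) return("rates must be finite and >= 0")
  if (p[1] < 0) return("positions must be non-negative")
  TRUE
})

#' Construct a MarkerMap
#'
#' @param chrom chromosome identifier.
#' @param positions marker positions in bp, strictly increasing.
#' @param rates recombination rate(s) in cM/Mb; a scalar is broadcast to all
#'   intervals.
#' @return A [MarkerMap-class] object.
#' @examples
#' m <- MarkerMap("chr1", c(1e6, 2e6, 4e6), rates = 2)
#' mapLengths(m)
#' @export
MarkerMap <- function(chrom, positions, rates = 1) {
  if (length(rates) == 1L) rates <- rep(rates, length(positions))
  new("MarkerMap", chrom = as.character(chrom),
      positions = as.numeric(positions), rates = as.numeric(rates))
}

#' @rdname MarkerMap
#' @param object,x a MarkerMap.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname MarkerMap
#' @export
setMethod("nMarkers", "MarkerMap", function(x) length(x@positions))

#' @rdname MarkerMap
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname MarkerMap
#' @export
setMethod("chromName", "MarkerMap", function(x) x@chrom)

#' @rdname MarkerMap
#' @export
setGeneric("mapPositions", function(x) standardGeneric("mapPositions"))

#' @rdname MarkerMap
#' @export
setMethod("mapPositions", "MarkerMap", function(x) x@positions)

#' @rdname MarkerMap
#' @export
setGeneric("mapRates", function(x) standardGeneric("mapRates"))

#' @rdname MarkerMap
#' @export
setMethod("mapRates", "MarkerMap", function(x) x@rates)

#' Inter-marker map lengths in Morgans
#'
#' Returns the Poisson crossover means for the L-1 intervals between
#' consecutive markers: m_j = d_j[Mb] x r_j[cM/Mb] / 100.
#'
#' @param x a MarkerMap.
#' @return numeric vector of length L-1 (empty for a single marker).
#' @export
setGeneric("mapLengths", function(x) standardGeneric("mapLengths"))

#' @rdname mapLengths
#' @export
setMethod("mapLengths", "MarkerMap", function(x) {
  L <- length(x@positions)
  if (L < 2L) return(numeric(0))
  diff(x@positions) / 1e6 * x@rates[-1L] / 100
})

setMethod("show", "MarkerMap", function(object) {
  L <- nMarkers(object)
  cat("MarkerMap on", object@chrom, "with", L, "markers\n")
  cat("  positions (bp):", paste(format(object@positions, trim = TRUE),
                                 collapse = ", "), "\n")
  if (L > 1L) {
    cat("  total map length:",
        format(sum(mapLengths(object)) * 100, digits = 4), "cM\n")
  }
})

#' HaplotypeFreqTable: population haplotype frequencies over a shared support
#'
#' Frequencies of the H distinct haplotypes (shared support) in two
#' populations A and B on one chromosome. Haplotypes are encoded as integer
#' bit-masks with marker j stored in bit j-1. Estimated tables (Dirichlet
#' posterior means) have strictly positive frequencies; tables holding known
#' simulation truth may contain zeros for haplotypes private to one
#' population.
#'
#' @slot chrom chromosome identifier.
#' @slot nMarkers number of markers L.
#' @slot support strictly increasing integer bit-masks of the H haplotypes.
#' @slot freqA,freqB per-haplotype frequencies in populations A and B.
#' @slot countA,countB observed copy counts behind estimated frequencies.
#' @slot sizeA,sizeB diploid reference panel sizes N_A, N_B.
#' @export
setClass("HaplotypeFreqTable", representation(
  chrom = "character",
  nMarkers = "integer",
  support = "integer",
  freqA = "numeric",
  freqB = "numeric",
  countA = "numeric",
  countB = "numeric",
  sizeA = "numeric",
  sizeB = "numeric"
))

setValidity("HaplotypeFreqTable", function(object) {
  H <- length(object@support)
  if (H < 1L) return("support must contain at least one haplotype")
  if (is.unsorted(object@support, strictly = TRUE)) {
    return("support bit-masks must be distinct and ascending")
  }
  L <- object@nMarkers
  if (L < 1L || L > 30L) return("nMarkers out of range")
  if (any(object@support < 0L) || any(object@support > 2^L - 1)) {
    return("support bit-masks exceed marker count")
  }
  for (s in c("freqA", "freqB", "countA", "countB")) {
    v <- slot(object, s)
    if (length(v) != H) return(paste(s, "must have one entry per haplotype"))
    if (any(!is.finite(v)) || any(v < 0)) return(paste(s, "must be >= 0"))
  }
  if (abs(sum(object@freqA) - 1) > 1e-9) return("freqA must sum to 1")
  if (abs(sum(object@freqB) - 1) > 1e-9) return("freqB must sum to 1")
  TRUE
})

#' Construct a HaplotypeFreqTable
#'
#' @param chrom chromosome identifier.
#' @param nMarkers number of markers L.
#' @param support integer bit-masks of the distinct haplotypes (ascending).
#' @param freqA,freqB frequencies per haplotype in each population.
#' @param countA,countB optional observed copy counts.
#' @param sizeA,sizeB optional diploid panel sizes.
#' @return A [HaplotypeFreqTable-class] object.
#' @examples
#' tab <- HaplotypeFreqTable("chr1", nMarkers = 2,
#'                           support = c(0L, 1L, 3L),
#'                           freqA = c(0.7, 0.2, 0.1),
#'                           freqB = c(0.1, 0.2, 0.7))
#' marginalFrequency(tab, "A", 2, 2, 1L)
#' @export
HaplotypeFreqTable <- function(chrom, nMarkers, support, freqA, freqB,
                               countA = rep(0, length(support)),
                               countB = rep(0, length(support)),
                               sizeA = 0, sizeB = 0) {
  o <- order(support)
  new("HaplotypeFreqTable", chrom = as.character(chrom),
      nMarkers = as.integer(nMarkers), support = as.integer(support[o]),
      freqA = as.numeric(freqA[o]), freqB = as.numeric(freqB[o]),
      countA = as.numeric(countA[o]), countB = as.numeric(countB[o]),
      sizeA = as.numeric(sizeA), sizeB = as.numeric(sizeB))
}

#' @rdname HaplotypeFreqTable
#' @param x a HaplotypeFreqTable.
#' @export
setMethod("nMarkers", "HaplotypeFreqTable", function(x) x@nMarkers)

#' @rdname HaplotypeFreqTable
#' @export
setMethod("chromName", "HaplotypeFreqTable", function(x) x@chrom)

#' @rdname HaplotypeFreqTable
#' @export
setGeneric("supportHaps", function(x) standardGeneric("supportHaps"))

#' @rdname HaplotypeFreqTable
#' @export
setMethod("supportHaps", "HaplotypeFreqTable", function(x) x@support)

#' Population haplotype frequencies from a table
#'
#' @param x a HaplotypeFreqTable.
#' @param population `"A"` or `"B"`.
#' @return numeric vector of H frequencies, in support order.
#' @export
popFrequencies <- function(x, population = c("A", "B")) {
  population <- match.arg(population)
  if (population == "A") x@freqA else x@freqB
}

setMethod("show", "HaplotypeFreqTable", function(object) {
  H <- length(object@support)
  cat("HaplotypeFreqTable on", object@chrom, "-", H, "haplotypes x",
      object@nMarkers, "markers\n")
  n <- min(H, 8L)
  df <- data.frame(
    haplotype = vapply(object@support[seq_len(n)], hapToString,
                       character(1), L = object@nMarkers),
    freq_A = signif(object@freqA[seq_len(n)], 4),
    freq_B = signif(object@freqB[seq_len(n)], 4))
  print(df, row.names = FALSE)
  if (H > n) cat("  ...", H - n, "more\n")
})

#' Diplotype: the pair of haplotypes carried by one individual
#'
#' One haplotype bit-mask per chromosome for the maternally and paternally
#' inherited copies. Labels are exchangeable (autosomes): all class
#' likelihoods are invariant under swapping the two copies.
#'
#' @slot hapM,hapP integer bit-masks, one per chromosome.
#' @export
setClass("Diplotype", representation(hapM = "integer", hapP = "integer"))

setValidity("Diplotype", function(object) {
  if (length(object@hapM) != length(object@hapP)) {
    return("hapM and hapP must have one entry per chromosome")
  }
  if (length(object@hapM) < 1L) return("at least one chromosome required")
  if (any(object@hapM < 0L) || any(object@hapP < 0L)) {
    return("haplotype bit-masks must be >= 0")
  }
  TRUE
})

#' Construct a Diplotype
#'
#' @param hapM,hapP integer haplotype bit-masks, one per chromosome.
#' @return A [Diplotype-class] object.
#' @export
Diplotype <- function(hapM, hapP) {
  new("Diplotype", hapM = as.integer(hapM), hapP = as.integer(hapP))
}

setMethod("show", "Diplotype", function(object) {
  cat("Diplotype over", length(object@hapM), "chromosome(s)\n")
})

#' Genotype: unphased marker data for one individual
#'
#' Per chromosome, a vector of genotype codes in {0, 1, 2} counting copies of
#' allele 1 at each marker. Phase is unknown; likelihoods marginalize over
#' all compatible diplotypes.
#'
#' @slot codes list with one integer vector of codes per chromosome.
#' @export
setClass("Genotype", representation(codes = "list"))

setValidity("Genotype", function(object) {
  if (length(object@codes) < 1L) return("at least one chromosome required")
  ok <- vapply(object@codes, function(v) {
    is.numeric(v) && length(v) >= 1L && all(v %in% 0:2)
  }, logical(1))
  if (!all(ok)) return("genotype codes must be vectors over {0, 1, 2}")
  TRUE
})

#' Construct a Genotype
#'
#' @param codes list of per-chromosome integer vectors with entries 0/1/2,
#'   or a single vector for one chromosome.
#' @return A [Genotype-class] object.
#' @export
Genotype <- function(codes) {
  if (!is.list(codes)) codes <- list(codes)
  new("Genotype", codes = lapply(codes, as.integer))
}

setMethod("show", "Genotype", function(object) {
  cat("Genotype over", length(object@codes), "chromosome(s),",
      sum(lengths(object@codes)), "markers\n")
})

#' ClassPosterior: posterior probabilities over the six genealogical classes
#'
#' The six classes are a (pure B), b (backcross with A), c (F1), d (pure A),
#' e (backcross with B) and f (F2).
#'
#' @slot prior prior probabilities, named a-f, summing to 1.
#' @slot logLik per-class log-likelihoods (natural log).
#' @slot posterior posterior probabilities, named a-f, summing to 1.
#' @export
setClass("ClassPosterior", representation(
  prior = "numeric",
  logLik = "numeric",
  posterior = "numeric"
))

setValidity("ClassPosterior", function(object) {
  for (s in c("prior", "logLik", "posterior")) {
    if (length(slot(object, s)) != 6L) return(paste(s, "must have length 6"))
  }
  if (any(object@prior < 0) || abs(sum(object@prior) - 1) > 1e-9) {
    return("prior must be non-negative and sum to 1")
  }
  if (any(object@posterior < 0) || abs(sum(object@posterior) - 1) > 1e-9) {
    return("posterior must be non-negative and sum to 1")
  }
  TRUE
})

#' @rdname ClassPosterior-class
#' @param x a ClassPosterior.
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @rdname ClassPosterior-class
#' @export
setMethod("posteriorProbs", "ClassPosterior", function(x) x@posterior)

#' @rdname ClassPosterior-class
#' @export
setGeneric("logLiks", function(x) standardGeneric("logLiks"))

#' @rdname ClassPosterior-class
#' @export
setMethod("logLiks", "ClassPosterior", function(x) x@logLik)

#' @rdname ClassPosterior-class
#' @export
setGeneric("priorProbs", function(x) standardGeneric("priorProbs"))

#' @rdname ClassPosterior-class
#' @export
setMethod("priorProbs", "ClassPosterior", function(x) x@prior)

#' Maximum a posteriori genealogical class
#'
#' @param x a ClassPosterior.
#' @return single character, one of `"a"`-`"f"`.
#' @export
setGeneric("mapClass", function(x) standardGeneric("mapClass"))

#' @rdname mapClass
#' @export
setMethod("mapClass", "ClassPosterior", function(x) {
  CLASS_LABELS[which.max(x@posterior)]
})

setMethod("show", "ClassPosterior", function(object) {
  cat("ClassPosterior (MAP class:", mapClass(object), ")\n")
  print(round(object@posterior, 4))
})
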