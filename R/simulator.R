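## Factorial simulator: haplotype panels via a switching process, Dirichlet
## haplotype frequencies, recombinant gametes, per-class diplotypes, and the
## full factorial study design.

FREQ_MODELS <- c("alpha1", "alpha5", "w5", "w20")

#' The factorial simulation design
#'
#' Enumerates every combination of the study factors: chromosomes
#' K in {1, 2, 5, 10, 20}; loci per chromosome L in {1, 5, 10}; expected
#' recombination frequency between the first and last locus R in {1, 25, 50}
#' cM; distinct haplotypes per population h in {5, 10, 15}; switch rate
#' c in {0.1, 1, L/2}; and four haplotype-frequency models (symmetric
#' Dirichlet alpha = 1 or 5, nonsymmetric with weight w = 5 or 20). For
#' L = 1 the only meaningful factors are K and the frequency model (Beta
#' distributions over the two alleles), giving 5 x 4 = 20 designs; for
#' L > 1 there are 5 x 2 x 3 x 3 x 3 x 4 = 1080, 1100 in total. Chromosome
#' length is fixed at 240 Mb and the recombination rate at 1.2 cM/Mb.
#'
#' @return data.frame with one row per design: columns `K`, `L`, `R`, `h`,
#'   `c`, `freqModel`, `chromLength`, `rate`. For L = 1 rows, `R` and `c`
#'   are `NA` and `h` is 2.
#' @examples
#' d <- factorialDesign()
#' nrow(d)              # 1100
#' sum(d$L > 1)         # 1080
#' @export
factorialDesign <- function() {
  big <- expand.grid(freqModel = FREQ_MODELS, cFactor = c("0.1", "1", "L/2"),
                     h = c(5, 10, 15), R = c(1, 25, 50), L = c(5, 10),
                     K = c(1, 2, 5, 10, 20), stringsAsFactors = FALSE)
  big <- big[, c("K", "L", "R", "h", "cFactor", "freqModel")]
  big$c <- numeric(nrow(big))
  half <- big$cFactor == "L/2"
  big$c[half] <- big$L[half] / 2
  big$c[!half] <- as.numeric(big$cFactor[!half])
  big$cFactor <- NULL
  small <- expand.grid(freqModel = FREQ_MODELS, K = c(1, 2, 5, 10, 20),
                       stringsAsFactors = FALSE)
  small <- data.frame(K = small$K, L = 1, R = NA_real_, h = 2,
                      freqModel = small$freqModel, c = NA_real_)
  out <- rbind(big, small)
  out <- out[, c("K", "L", "R", "h", "c", "freqModel")]
  out$chromLength <- 240e6
  out$rate <- 1.2
  rownames(out) <- NULL
  out
}

#' Marker map for one design
#'
#' L markers equally spaced so that the map length between the first and
#' last marker is R cM at the given uniform rate, centered on the
#' chromosome. For L = 1, a single marker at the chromosome midpoint.
#'
#' @param L number of markers.
#' @param R expected recombination frequency (cM) between first and last
#'   marker; ignored for L = 1.
#' @param chromLength chromosome length in bp (default 240 Mb).
#' @param rate recombination rate in cM/Mb (default 1.2).
#' @param chrom chromosome identifier.
#' @return A [MarkerMap-class].
#' @examples
#' makeDesignMap(10, 50)
#' @export
makeDesignMap <- function(L, R, chromLength = 240e6, rate = 1.2,
                          chrom = "chr1") {
  L <- as.integer(L)
  if (L == 1L) {
    return(MarkerMap(chrom, chromLength / 2, rates = rate))
  }
  spanBp <- R / rate * 1e6
  if (spanBp > chromLength) {
    stop("a span of ", R, " cM at ", rate,
         " cM/Mb exceeds the chromosome length")
  }
  pos <- seq((chromLength - spanBp) / 2, (chromLength + spanBp) / 2,
             length.out = L)
  MarkerMap(chrom, pos, rates = rate)
}

#' Simulate a panel of distinct haplotypes by a switching process
#'
#' Each haplotype starts with a Bernoulli(1/2) allele at marker 1; each
#' subsequent marker copies its left neighbour with probability 1 - p and
#' flips with probability p = c / L, mimicking the decay of linkage
#' disequilibrium with distance. Colliding haplotypes are redrawn until the
#' h panel haplotypes are distinct.
#'
#' @param h number of distinct haplotypes.
#' @param L number of markers.
#' @param c switch rate (expected number of flips per haplotype).
#' @param maxTries redraw budget for enforcing distinctness.
#' @return integer vector of h distinct haplotype bit-masks.
#' @export
simulateHaplotypePanel <- function(h, L, c = 0.1, maxTries = 10000L) {
  if (h > 2^L) stop("cannot draw ", h, " distinct haplotypes from ",
                    2^L, " possibilities")
  p <- c / L
  draw <- function() {
    bits <- integer(L)
    bits[1L] <- rbinom(1L, 1L, 0.5)
    if (L > 1L) {
      flips <- rbinom(L - 1L, 1L, p)
      bits[-1L] <- bitwXor(bits[1L], cumsum(flips) %% 2L)
    }
    bitsToHap(bits)
  }
  haps <- integer(0)
  tries <- 0L
  while (length(haps) < h) {
    cand <- draw()
    if (cand %in% haps) {
      tries <- tries + 1L
      if (tries > maxTries) {
        stop("could not draw ", h, " distinct haplotypes within ",
             maxTries, " redraws")
      }
    } else {
      haps <- c(haps, cand)
    }
  }
  haps
}

#' Draw population haplotype frequencies
#'
#' Dirichlet frequencies over the h panel haplotypes: symmetric with
#' alpha = 1 (`"alpha1"`) or alpha = 5 (`"alpha5"`), or nonsymmetric
#' (`"w5"`, `"w20"`) with alpha_1 = 0.7 w and alpha_i = 0.3 w / (h - 1) for
#' i > 1, so one haplotype is common (mean 0.7) and the rest share the
#' remainder. For h = 2 these reduce to the four Beta settings of the
#' single-locus design.
#'
#' @param h number of haplotypes.
#' @param model one of `"alpha1"`, `"alpha5"`, `"w5"`, `"w20"`.
#' @return frequency vector of length h (positive, sums to 1).
#' @export
simulateFrequencies <- function(h, model = c("alpha1", "alpha5", "w5",
                                             "w20")) {
  model <- match.arg(model)
  if (h < 2L) stop("need at least 2 haplotype categories")
  alpha <- switch(model,
                  alpha1 = rep(1, h),
                  alpha5 = rep(5, h),
                  w5 = c(0.7 * 5, rep(0.3 * 5 / (h - 1), h - 1)),
                  w20 = c(0.7 * 20, rep(0.3 * 20 / (h - 1), h - 1)))
  x <- rgamma(h, shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate one recombinant gamete
#'
#' An F1 meiosis between a pure population-A and a pure population-B
#' chromosome: the founder origin at marker 1 is Bernoulli(1/2) and each
#' inter-marker interval switches origin with probability
#' [probStateChange()] of its map length (equivalent to Poisson crossover
#' counts mod 2). The gamete copies each marker's allele from the parent
#' matching its ancestry.
#'
#' @param hapA,hapB parental haplotype bit-masks (from populations A and B).
#' @param map a [MarkerMap-class].
#' @return integer haplotype bit-mask.
#' @export
simulateRecombinantGamete <- function(hapA, hapB, map) {
  simulateRecombinantGametes(hapA, hapB, map, n = 1L)
}

#' @rdname simulateRecombinantGamete
#' @param n number of gametes; `hapA`/`hapB` are recycled to length n.
#' @export
simulateRecombinantGametes <- function(hapA, hapB, map, n = length(hapA)) {
  L <- nMarkers(map)
  hapA <- rep_len(as.integer(hapA), n)
  hapB <- rep_len(as.integer(hapB), n)
  if (any(hapA > 2^L - 1) || any(hapB > 2^L - 1)) {
    stop("parental haplotypes exceed the marker range")
  }
  founder <- rbinom(n, 1L, 0.5)
  if (L == 1L) {
    zmask <- founder
  } else {
    P <- probStateChange(mapLengths(map))
    changes <- matrix(rbinom(n * (L - 1L), 1L, rep(P, each = n)), nrow = n)
    if (L > 2L) {
      for (j in 2:(L - 1L)) changes[, j] <- changes[, j - 1L] + changes[, j]
    }
    zbits <- cbind(founder, (founder + changes) %% 2L)
    zmask <- as.integer(zbits %*% 2^(0:(L - 1L)))
  }
  bitwOr(bitwAnd(hapA, bitwNot(zmask)), bitwAnd(hapB, zmask))
}

## Internal: per-class copy recipe. Draws for one chromosome, vectorized
## over individuals. drawA/drawB sample from the population haplotype
## distributions; rec() produces recombinant gametes with fresh founders.
simulateChromPair <- function(classes, drawA, drawB, rec) {
  n <- length(classes)
  hapM <- integer(n); hapP <- integer(n)
  for (g in CLASS_LABELS) {
    idx <- which(classes == g)
    if (length(idx) == 0L) next
    k <- length(idx)
    mp <- switch(g,
                 a = list(drawB(k), drawB(k)),
                 b = list(drawA(k), rec(k)),
                 c = list(drawA(k), drawB(k)),
                 d = list(drawA(k), drawA(k)),
                 e = list(drawB(k), rec(k)),
                 f = list(rec(k), rec(k)))
    hapM[idx] <- mp[[1L]]
    hapP[idx] <- mp[[2L]]
  }
  list(hapM = hapM, hapP = hapP)
}

#' Simulate a diplotype for one individual of a given class
#'
#' Class semantics: a draws both copies from population B; d both from A;
#' c one from each (F1); b one copy from A plus one recombinant gamete
#' (with independently drawn A and B parents); e one from B plus one
#' recombinant; f two independent recombinant gametes (four independent
#' founders, the non-inbred F2). Chromosomes are independent.
#'
#' @param g class, one of `"a"`-`"f"`.
#' @param tables list of [HaplotypeFreqTable-class], one per chromosome
#'   (frequencies used as sampling weights).
#' @param maps list of [MarkerMap-class], one per chromosome.
#' @return A [Diplotype-class].
#' @export
simulateIndividual <- function(g, tables, maps) {
  g <- if (is.numeric(g)) CLASS_LABELS[g] else match.arg(g, CLASS_LABELS)
  tables <- asChromList(tables, "tables"); maps <- asChromList(maps, "maps")
  K <- length(tables)
  if (length(maps) != K) stop("need one map per frequency table")
  hapM <- integer(K); hapP <- integer(K)
  for (i in seq_len(K)) {
    tab <- tables[[i]]
    drawA <- function(k) sampleHaps(tab, "A", k)
    drawB <- function(k) sampleHaps(tab, "B", k)
    rec <- function(k) simulateRecombinantGametes(sampleHaps(tab, "A", k),
                                                 sampleHaps(tab, "B", k),
                                                 maps[[i]], n = k)
    pair <- simulateChromPair(g, drawA, drawB, rec)
    hapM[i] <- pair$hapM; hapP[i] <- pair$hapP
  }
  Diplotype(hapM, hapP)
}

## Internal: sample k haplotypes from one population of a table.
sampleHaps <- function(table, population, k) {
  f <- popFrequencies(table, population)
  table@support[sample.int(length(f), k, replace = TRUE, prob = f)]
}

#' Compose a diplotype from externally supplied haplotype pools
#'
#' Same class semantics as [simulateIndividual()], but parents are drawn
#' uniformly without replacement from user-supplied haplotype pools (for
#' example, samples from a coalescent simulation) instead of from fitted
#' frequency distributions.
#'
#' @param poolA,poolB integer vectors of at least 2 haplotype bit-masks.
#' @param g class, one of `"a"`-`"f"`.
#' @param maps list of [MarkerMap-class], one per chromosome; pools are
#'   reused across chromosomes only when one chromosome is given.
#' @return A [Diplotype-class].
#' @export
composeFromPools <- function(poolA, poolB, g, maps) {
  g <- if (is.numeric(g)) CLASS_LABELS[g] else match.arg(g, CLASS_LABELS)
  maps <- asChromList(maps, "maps")
  if (length(poolA) < 2L || length(poolB) < 2L) {
    stop("each pool must contain at least 2 haplotypes")
  }
  K <- length(maps)
  hapM <- integer(K); hapP <- integer(K)
  for (i in seq_len(K)) {
    dA <- sample(as.integer(poolA), 2L, replace = FALSE)
    dB <- sample(as.integer(poolB), 2L, replace = FALSE)
    pair <- switch(g,
      a = list(dB[1L], dB[2L]),
      b = list(dA[1L], simulateRecombinantGametes(dA[2L], dB[1L], maps[[i]],
                                                  n = 1L)),
      c = list(dA[1L], dB[1L]),
      d = list(dA[1L], dA[2L]),
      e = list(dB[1L], simulateRecombinantGametes(dA[1L], dB[2L], maps[[i]],
                                                  n = 1L)),
      f = list(simulateRecombinantGametes(dA[1L], dB[1L], maps[[i]], n = 1L),
               simulateRecombinantGametes(dA[2L], dB[2L], maps[[i]],
                                          n = 1L)))
    hapM[i] <- pair[[1L]]; hapP[i] <- pair[[2L]]
  }
  Diplotype(hapM, hapP)
}

#' Simulate a full dataset under one design
#'
#' For each of K chromosomes, draws two panels of h distinct haplotypes
#' (switching process), Dirichlet frequencies for each population over its
#' panel, and builds the truth [HaplotypeFreqTable-class] on the union
#' support (haplotypes private to one population have frequency zero
#' there). Individuals are assigned classes uniformly (or as supplied) and
#' their diplotypes simulated per class.
#'
#' @param n number of individuals.
#' @param K,L,R,h,c,freqModel design factors (see [factorialDesign()]).
#' @param chromLength,rate design constants.
#' @param classes optional vector of true classes (default: uniform draw).
#' @return list with `hapM`, `hapP` (n x K integer matrices), `classes`,
#'   `maps`, `tables`.
#' @export
simulateDataset <- function(n, K = 20, L = 10, R = 50, h = 10, c = 0.1,
                            freqModel = "alpha1", chromLength = 240e6,
                            rate = 1.2, classes = NULL) {
  if (is.null(classes)) {
    classes <- sample(CLASS_LABELS, n, replace = TRUE)
  }
  stopifnot(length(classes) == n, all(classes %in% CLASS_LABELS))
  L <- as.integer(L)
  hapM <- matrix(0L, n, K); hapP <- matrix(0L, n, K)
  maps <- vector("list", K); tables <- vector("list", K)
  for (i in seq_len(K)) {
    map <- makeDesignMap(L, R, chromLength, rate,
                         chrom = paste0("chr", i))
    panelA <- simulateHaplotypePanel(h, L, c = if (is.na(c)) 0 else c)
    panelB <- simulateHaplotypePanel(h, L, c = if (is.na(c)) 0 else c)
    if (L == 1L) {  # single-locus design: the two alleles are the panel
      panelA <- c(0L, 1L); panelB <- c(0L, 1L)
    }
    fA <- simulateFrequencies(length(panelA), freqModel)
    fB <- simulateFrequencies(length(panelB), freqModel)
    support <- sort(unique(c(panelA, panelB)))
    freqA <- numeric(length(support)); freqB <- numeric(length(support))
    freqA[match(panelA, support)] <- fA
    freqB[match(panelB, support)] <- fB
    tab <- HaplotypeFreqTable(paste0("chr", i), L, support, freqA, freqB)
    drawA <- function(k) sampleHaps(tab, "A", k)
    drawB <- function(k) sampleHaps(tab, "B", k)
    rec <- function(k) simulateRecombinantGametes(drawA(k), drawB(k), map,
                                                  n = k)
    pair <- simulateChromPair(classes, drawA, drawB, rec)
    hapM[, i] <- pair$hapM; hapP[, i] <- pair$hapP
    maps[[i]] <- map; tables[[i]] <- tab
  }
  list(hapM = hapM, hapP = hapP, classes = classes, maps = maps,
       tables = tables)
}
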