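## Full-likelihood engine: exact likelihoods of phased/unphased marker data
## under the six genealogical classes, and the Bayesian posterior.

## Internal: full-haplotype frequency lookup (0 for haplotypes off-support).
lookupFreq <- function(table, haps, population) {
  f <- popFrequencies(table, population)
  idx <- match(as.integer(haps), table@support)
  out <- f[idx]
  out[is.na(idx)] <- 0
  out
}

#' Probability of a haplotype given an ancestry state
#'
#' f(x | z): with the chromosome partitioned into the maximal segments of
#' constant population origin in z, the product over segments of the
#' matching population's marginal sub-haplotype frequency. For z all-A this
#' is f^A(x) and for z all-B it is f^B(x).
#'
#' @param hap haplotype: integer bit-mask or 0/1 vector of length L.
#' @param state ancestry state: integer bit-mask or 0/1 vector of length L.
#' @param table a [HaplotypeFreqTable-class].
#' @return probability in [0, 1].
#' @export
seqProbGivenState <- function(hap, state, table) {
  L <- nMarkers(table)
  x <- asBitmask(hap, L)
  z <- asBitmask(state, L)
  .segProbBatch(x, z, L, table@support, table@freqA, table@freqB)[1L]
}

#' Likelihood of a recombinant haplotype
#'
#' Probability of observing haplotype x on one chromosome copy of a
#' recombinant gamete: the sum over all 2^L ancestry states z of
#' f(x | z) Q(z | d, r). The sum is evaluated by an exact dynamic program
#' over ancestry segments (cost quadratic in L rather than 2^L).
#'
#' @param hap haplotype bit-mask or 0/1 vector.
#' @param map a [MarkerMap-class].
#' @param table a [HaplotypeFreqTable-class] on the same markers.
#' @param cap largest L allowed (see [enumerateAncestryStates()]).
#' @return probability in [0, 1]; sums to 1 over all 2^L haplotypes.
#' @export
recombinantLikelihood <- function(hap, map, table, cap = 10L) {
  recombinantLikelihoods(asBitmask(hap, nMarkers(map)), map, table,
                         cap = cap)[1L]
}

#' @rdname recombinantLikelihood
#' @param haps integer vector of haplotype bit-masks.
#' @export
recombinantLikelihoods <- function(haps, map, table, cap = 10L) {
  L <- nMarkers(map)
  if (nMarkers(table) != L) stop("map and frequency table disagree on L")
  enumerateAncestryStates(L, cap = cap)  # enforces the marker cap
  P <- probStateChange(mapLengths(map))
  .recombLikBatch(as.integer(haps), L, table@support,
                  table@freqA, table@freqB, P)
}

## Internal: per-chromosome likelihoods of one diplotype under all six
## classes, on the linear scale. Returns a named 6-vector.
chromClassLiks <- function(xm, xp, map, table, cap = 10L) {
  fAM <- lookupFreq(table, xm, "A"); fAP <- lookupFreq(table, xp, "A")
  fBM <- lookupFreq(table, xm, "B"); fBP <- lookupFreq(table, xp, "B")
  rec <- recombinantLikelihoods(c(xm, xp), map, table, cap = cap)
  recM <- rec[1L]; recP <- rec[2L]
  I <- xm != xp
  two <- if (I) 2 else 1
  c(a = two * fBM * fBP,
    b = if (I) fAM * recP + fAP * recM else fAM * recP,
    c = if (I) fAM * fBP + fAP * fBM else fAM * fBP,
    d = two * fAM * fAP,
    e = if (I) fBM * recP + fBP * recM else fBM * recP,
    f = two * recM * recP)
}

## Internal: coerce maps/tables arguments to lists of length K.
asChromList <- function(x, what) {
  if (is(x, "MarkerMap") || is(x, "HaplotypeFreqTable")) x <- list(x)
  if (!is.list(x)) stop(what, " must be a list with one element per chromosome")
  x
}

#' Log-likelihood of a diplotype under one genealogical class
#'
#' The six classes are: a both copies from population B; b one copy from A
#' and one recombinant; c one copy from A and one from B (F1); d both
#' copies from A; e one copy from B and one recombinant; f both copies
#' recombinant (F2). Likelihoods multiply across chromosomes; when the two
#' copies differ the ordered assignments are symmetrized (a factor of 2 for
#' classes a, c, d, f and an explicit two-term sum for b, e), so all
#' likelihoods are invariant to swapping the maternal and paternal labels.
#'
#' @param dip a [Diplotype-class] (one haplotype bit-mask per chromosome in
#'   each of `hapM`, `hapP`).
#' @param g class: one of `"a"`-`"f"` or an integer 1-6.
#' @param maps list of [MarkerMap-class], one per chromosome.
#' @param tables list of [HaplotypeFreqTable-class], one per chromosome.
#' @param cap marker cap per chromosome.
#' @return log-likelihood (natural log; `-Inf` only if some required
#'   frequency is exactly zero).
#' @export
classLikelihood <- function(dip, g, maps, tables, cap = 10L) {
  stopifnot(is(dip, "Diplotype"))
  g <- if (is.numeric(g)) CLASS_LABELS[g] else match.arg(g, CLASS_LABELS)
  maps <- asChromList(maps, "maps"); tables <- asChromList(tables, "tables")
  K <- length(dip@hapM)
  if (length(maps) != K || length(tables) != K) {
    stop("need one map and one frequency table per chromosome")
  }
  ll <- 0
  for (i in seq_len(K)) {
    ll <- ll + log(chromClassLiks(dip@hapM[i], dip@hapP[i],
                                  maps[[i]], tables[[i]], cap = cap)[[g]])
  }
  ll
}

#' Posterior probabilities over the six genealogical classes
#'
#' Bayes' rule over the class likelihoods: P(G = g | data) proportional to
#' pi_g L(data | G = g), normalized over the six classes. For a
#' [Diplotype-class] the phased likelihood is used; for a
#' [Genotype-class] the likelihood marginalizes over every diplotype
#' compatible with the genotype codes (phase integration).
#'
#' @param x a [Diplotype-class] or [Genotype-class].
#' @param maps list of [MarkerMap-class], one per chromosome.
#' @param tables list of [HaplotypeFreqTable-class], one per chromosome.
#' @param prior prior over the classes a-f; default discrete uniform.
#' @param cap marker cap per chromosome.
#' @return A [ClassPosterior-class].
#' @examples
#' map <- MarkerMap("chr1", c(1e6, 2e6), rates = 10)
#' tab <- HaplotypeFreqTable("chr1", 2, c(0L, 3L), c(0.9, 0.1), c(0.1, 0.9))
#' posteriorOverClasses(Diplotype(0L, 3L), map, tab)
#' @export
setGeneric("posteriorOverClasses",
           function(x, maps, tables, prior = rep(1 / 6, 6), cap = 10L)
             standardGeneric("posteriorOverClasses"))

checkPrior <- function(prior) {
  if (length(prior) != 6L || any(prior < 0) || any(!is.finite(prior)) ||
      abs(sum(prior) - 1) > 1e-9) {
    stop("prior must be 6 non-negative probabilities summing to 1 (got ",
         paste(signif(prior, 4), collapse = ", "), ")")
  }
  as.numeric(prior)
}

makePosterior <- function(logLik, prior) {
  lp <- log(prior) + logLik
  lp[prior == 0] <- -Inf
  m <- max(lp)
  post <- exp(lp - m)
  post <- post / sum(post)
  new("ClassPosterior", prior = setNames(prior, CLASS_LABELS),
      logLik = setNames(logLik, CLASS_LABELS),
      posterior = setNames(post, CLASS_LABELS))
}

## Internal: warn when an individual carries haplotypes at (or below) the
## estimation pseudocount floor.
warnRareHaps <- function(haps, table) {
  L <- nMarkers(table)
  idx <- match(as.integer(haps), table@support)
  off <- unique(haps[is.na(idx)])
  if (length(off) > 0L) {
    warning("haplotype(s) ", paste(vapply(off, hapToString, character(1),
                                          L = L), collapse = ", "),
            " on ", chromName(table), " are absent from the support",
            call. = FALSE)
  }
  if (table@sizeA + table@sizeB > 0) {
    seen <- idx[!is.na(idx)]
    floorHaps <- seen[table@countA[seen] + table@countB[seen] == 0]
    if (length(floorHaps) > 0L) {
      warning("haplotype(s) ",
              paste(vapply(table@support[unique(floorHaps)], hapToString,
                           character(1), L = L), collapse = ", "),
              " on ", chromName(table),
              " have pseudocount-only frequency", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' @rdname posteriorOverClasses
#' @export
setMethod("posteriorOverClasses", "Diplotype",
          function(x, maps, tables, prior = rep(1 / 6, 6), cap = 10L) {
  prior <- checkPrior(prior)
  maps <- asChromList(maps, "maps"); tables <- asChromList(tables, "tables")
  K <- length(x@hapM)
  if (length(maps) != K || length(tables) != K) {
    stop("need one map and one frequency table per chromosome")
  }
  ll <- setNames(numeric(6), CLASS_LABELS)
  for (i in seq_len(K)) {
    warnRareHaps(c(x@hapM[i], x@hapP[i]), tables[[i]])
    ll <- ll + log(chromClassLiks(x@hapM[i], x@hapP[i],
                                  maps[[i]], tables[[i]], cap = cap))
  }
  makePosterior(ll, prior)
})

#' @rdname posteriorOverClasses
#' @export
setMethod("posteriorOverClasses", "Genotype",
          function(x, maps, tables, prior = rep(1 / 6, 6), cap = 10L) {
  prior <- checkPrior(prior)
  ll <- vapply(CLASS_LABELS, function(g)
    unphasedClassLikelihood(x, g, maps, tables, cap = cap), numeric(1))
  makePosterior(ll, prior)
})

#' Enumerate diplotypes compatible with an unphased genotype
#'
#' For genotype codes over L markers with k heterozygous sites, the
#' unordered pairs of haplotypes whose allele sums reproduce the codes:
#' 2^(k-1) pairs for k >= 1, one for k = 0. The first heterozygous site is
#' fixed to allele 0 on the first member of each pair, which enumerates each
#' unordered pair exactly once.
#'
#' @param codes integer vector over {0, 1, 2}.
#' @return two-column integer matrix of haplotype bit-masks; each row is one
#'   compatible unordered pair.
#' @examples
#' enumerateCompatibleDiplotypes(c(1L, 1L))
#' @export
enumerateCompatibleDiplotypes <- function(codes) {
  codes <- as.integer(codes)
  if (!all(codes %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  L <- length(codes)
  base <- sum((codes == 2L) * 2^(seq_len(L) - 1L))
  het <- which(codes == 1L)
  k <- length(het)
  if (k == 0L) {
    return(matrix(as.integer(c(base, base)), ncol = 2L,
                  dimnames = list(NULL, c("hapM", "hapP"))))
  }
  hetMask <- sum(2^(het - 1L))
  free <- het[-1L]
  n <- 2L^(k - 1L)
  m1 <- integer(n)
  if (k > 1L) {
    combos <- as.matrix(expand.grid(rep(list(0:1), k - 1L)))
    m1 <- as.integer(combos %*% 2^(free - 1L))
  }
  hapM <- as.integer(base + m1)
  hapP <- as.integer(base + (hetMask - m1))
  cbind(hapM = hapM, hapP = hapP)
}

#' Log-likelihood of an unphased genotype under one class
#'
#' Phase-integrated likelihood: per chromosome, the sum over all compatible
#' unordered diplotype pairs of the phased class likelihood; chromosomes
#' multiply. For a fully homozygous genotype this equals the phased
#' likelihood of its unique diplotype.
#'
#' @param genotype a [Genotype-class].
#' @inheritParams classLikelihood
#' @return log-likelihood (natural log).
#' @export
unphasedClassLikelihood <- function(genotype, g, maps, tables, cap = 10L) {
  stopifnot(is(genotype, "Genotype"))
  g <- if (is.numeric(g)) CLASS_LABELS[g] else match.arg(g, CLASS_LABELS)
  maps <- asChromList(maps, "maps"); tables <- asChromList(tables, "tables")
  K <- length(genotype@codes)
  if (length(maps) != K || length(tables) != K) {
    stop("need one map and one frequency table per chromosome")
  }
  ll <- 0
  for (i in seq_len(K)) {
    pairs <- enumerateCompatibleDiplotypes(genotype@codes[[i]])
    tot <- sum(vapply(seq_len(nrow(pairs)), function(r) {
      chromClassLiks(pairs[r, 1L], pairs[r, 2L],
                     maps[[i]], tables[[i]], cap = cap)[[g]]
    }, numeric(1)))
    ll <- ll + log(tot)
  }
  ll
}

#' Batch classification of phased individuals
#'
#' Vectorized full-likelihood posteriors for N individuals with K
#' chromosomes each. Recombinant-haplotype likelihoods are computed once per
#' distinct haplotype per chromosome.
#'
#' @param hapM,hapP integer matrices (individuals x chromosomes) of
#'   haplotype bit-masks.
#' @param maps list of [MarkerMap-class], one per chromosome.
#' @param tables list of [HaplotypeFreqTable-class], one per chromosome.
#' @param prior prior over classes; default uniform.
#' @param cap marker cap per chromosome.
#' @param ids individual identifiers (default 1..N).
#' @return data.frame with columns `individual`, `P_a`..`P_f`, `map_class`,
#'   `log10_lik_a`..`log10_lik_f` and `method = "full"`.
#' @export
classifyIndividuals <- function(hapM, hapP, maps, tables,
                                prior = rep(1 / 6, 6), cap = 10L,
                                ids = NULL) {
  prior <- checkPrior(prior)
  hapM <- as.matrix(hapM); hapP <- as.matrix(hapP)
  stopifnot(all(dim(hapM) == dim(hapP)))
  maps <- asChromList(maps, "maps"); tables <- asChromList(tables, "tables")
  N <- nrow(hapM); K <- ncol(hapM)
  if (length(maps) != K || length(tables) != K) {
    stop("need one map and one frequency table per chromosome")
  }
  ll <- matrix(0, N, 6L, dimnames = list(NULL, CLASS_LABELS))
  for (i in seq_len(K)) {
    tab <- tables[[i]]
    xm <- hapM[, i]; xp <- hapP[, i]
    uh <- unique(c(xm, xp))
    recU <- recombinantLikelihoods(uh, maps[[i]], tab, cap = cap)
    recM <- recU[match(xm, uh)]; recP <- recU[match(xp, uh)]
    fAM <- lookupFreq(tab, xm, "A"); fAP <- lookupFreq(tab, xp, "A")
    fBM <- lookupFreq(tab, xm, "B"); fBP <- lookupFreq(tab, xp, "B")
    I <- xm != xp
    l2 <- ifelse(I, log(2), 0)
    ll[, "a"] <- ll[, "a"] + l2 + log(fBM) + log(fBP)
    ll[, "d"] <- ll[, "d"] + l2 + log(fAM) + log(fAP)
    ll[, "f"] <- ll[, "f"] + l2 + log(recM) + log(recP)
    ll[, "c"] <- ll[, "c"] + log(ifelse(I, fAM * fBP + fAP * fBM, fAM * fBP))
    ll[, "b"] <- ll[, "b"] + log(ifelse(I, fAM * recP + fAP * recM,
                                        fAM * recP))
    ll[, "e"] <- ll[, "e"] + log(ifelse(I, fBM * recP + fBP * recM,
                                        fBM * recP))
  }
  lp <- sweep(ll, 2L, log(prior), "+")
  lp[, prior == 0] <- -Inf
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  out <- data.frame(individual = if (is.null(ids)) seq_len(N) else ids)
  for (g in CLASS_LABELS) out[[paste0("P_", g)]] <- post[, g]
  out$map_class <- CLASS_LABELS[max.col(post, ties.method = "first")]
  for (g in CLASS_LABELS) out[[paste0("log10_lik_", g)]] <- ll[, g] / log(10)
  out$method <- "full"
  out
}
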