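## Unlinked composite-likelihood baseline: per-locus genotype probabilities
## under the six classes with known allele frequencies and no MCMC,
## multiplied across loci as if all markers were independent.

## Gene-copy allele-1 frequencies (u, v) for one marker under each class:
## pure classes draw both copies from one population, the F1 one from each,
## a backcross one fixed copy plus one F1 gamete (frequency (pA+pB)/2), and
## the F2 two independent F1 gametes (the 1/4-1/2-1/4 origin mixture
## factorizes into independent copies).
copyFreqs <- function(pA, pB, g) {
  q <- (pA + pB) / 2
  switch(g,
         a = list(u = pB, v = pB),
         b = list(u = pA, v = q),
         c = list(u = pA, v = pB),
         d = list(u = pA, v = pA),
         e = list(u = pB, v = q),
         f = list(u = q, v = q),
         stop("unknown genealogical class: ", g))
}

#' Genotype probability at one marker under a genealogical class
#'
#' Probability of genotype code 0/1/2 (copies of allele 1) at a single
#' biallelic marker with allele-1 frequencies `pA` and `pB` in the two
#' populations, under the unlinked six-class model: each gene copy's
#' population of origin is determined by the class (both from one
#' population for pure classes, one from each for the F1, a 50:50 mixture
#' for copies descending through an F1 gamete) and copies are independent.
#'
#' @param code genotype code(s) in {0, 1, 2}.
#' @param pA,pB allele-1 frequencies in populations A and B, in (0, 1).
#' @param g class, one of `"a"`-`"f"` or 1-6.
#' @return probabilities; for fixed (pA, pB, g) the three codes sum to 1.
#' @examples
#' classGenotypeProb(1, pA = 0.9, pB = 0.1, g = "c")  # 0.82
#' @export
classGenotypeProb <- function(code, pA, pB, g) {
  if (!all(code %in% 0:2)) stop("genotype codes must be 0, 1 or 2")
  if (any(pA <= 0) || any(pA >= 1) || any(pB <= 0) || any(pB >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  g <- if (is.numeric(g)) CLASS_LABELS[g] else match.arg(g, CLASS_LABELS)
  cf <- copyFreqs(pA, pB, g)
  u <- cf$u; v <- cf$v
  p0 <- (1 - u) * (1 - v)
  p1 <- u * (1 - v) + v * (1 - u)
  p2 <- u * v
  ifelse(code == 0L, p0, ifelse(code == 1L, p1, p2))
}

#' Composite-likelihood posterior over genealogical classes
#'
#' The unlinked baseline classifier: genotype codes at all markers (across
#' all chromosomes) are treated as independent, so the class likelihood is
#' the product over markers of [classGenotypeProb()]. The marker map is
#' ignored entirely. With one marker per chromosome this coincides exactly
#' with the full-likelihood posterior.
#'
#' @param codes integer vector of genotype codes over all markers.
#' @param pA,pB allele-1 frequency per marker in populations A and B.
#' @param prior prior over classes; default uniform.
#' @return A [ClassPosterior-class].
#' @export
compositePosterior <- function(codes, pA, pB, prior = rep(1 / 6, 6)) {
  prior <- checkPrior(prior)
  M <- length(codes)
  if (length(pA) != M || length(pB) != M) {
    stop("need one allele frequency pair per marker")
  }
  ll <- vapply(CLASS_LABELS, function(g)
    sum(log(classGenotypeProb(codes, pA, pB, g))), numeric(1))
  makePosterior(ll, prior)
}

#' Batch composite-likelihood classification
#'
#' Vectorized [compositePosterior()] for N individuals.
#'
#' @param codes integer matrix (individuals x markers) of genotype codes.
#' @param pA,pB allele-1 frequency per marker (length = ncol(codes)).
#' @param prior prior over classes; default uniform.
#' @param ids individual identifiers (default 1..N).
#' @return data.frame in the same schema as [classifyIndividuals()], with
#'   `method = "composite"`.
#' @export
classifyComposite <- function(codes, pA, pB, prior = rep(1 / 6, 6),
                              ids = NULL) {
  prior <- checkPrior(prior)
  codes <- as.matrix(codes)
  N <- nrow(codes); M <- ncol(codes)
  if (length(pA) != M || length(pB) != M) {
    stop("need one allele frequency pair per marker")
  }
  ll <- matrix(0, N, 6L, dimnames = list(NULL, CLASS_LABELS))
  for (g in CLASS_LABELS) {
    lp <- log(rbind(classGenotypeProb(rep(0L, M), pA, pB, g),
                    classGenotypeProb(rep(1L, M), pA, pB, g),
                    classGenotypeProb(rep(2L, M), pA, pB, g)))
    # sum over markers of lp[code + 1, marker]
    acc <- numeric(N)
    for (cd in 0:2) {
      sel <- codes == cd
      acc <- acc + as.numeric(sel %*% lp[cd + 1L, ])
    }
    ll[, g] <- acc
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
  out$method <- "composite"
  out
}

#' Genotype codes from phased haplotype matrices
#'
#' Collapses phased bit-mask matrices to the 0/1/2 genotype codes the
#' composite baseline consumes, concatenating markers across chromosomes.
#'
#' @param hapM,hapP integer matrices (individuals x chromosomes).
#' @param Ls markers per chromosome (one per column).
#' @return integer matrix (individuals x total markers).
#' @export
genotypesFromHaplotypes <- function(hapM, hapP, Ls) {
  hapM <- as.matrix(hapM); hapP <- as.matrix(hapP)
  stopifnot(all(dim(hapM) == dim(hapP)), length(Ls) == ncol(hapM))
  blocks <- lapply(seq_along(Ls), function(i) {
    L <- Ls[i]
    bitsM <- vapply(0:(L - 1L), function(b)
      bitwAnd(bitwShiftR(hapM[, i], b), 1L), integer(nrow(hapM)))
    bitsP <- vapply(0:(L - 1L), function(b)
      bitwAnd(bitwShiftR(hapP[, i], b), 1L), integer(nrow(hapP)))
    matrix(bitsM + bitsP, nrow = nrow(hapM))
  })
  do.call(cbind, blocks)
}
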