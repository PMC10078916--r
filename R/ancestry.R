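#' Probability of a change of population ancestry across an interval
#'
#' Under a no-interference model, crossovers on an interval of map length m
#' (Morgans) are Poisson(m). The population origin of the marker to the
#' right of the interval changes when the crossover count is odd:
#' P(m) = 1 - (e^-m (cosh m - 1) + e^-m), which equals the Haldane map
#' function (1 - e^-2m)/2.
#'
#' @param m map length(s) in Morgans, non-negative and finite.
#' @return probabilities in [0, 1/2).
#' @examples
#' probStateChange(0.02)
#' @export
probStateChange <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("map length must be non-negative and finite")
  }
  -expm1(-2 * m) / 2
}

#' Probability of an even, non-zero number of crossovers on an interval
#'
#' e^-m (cosh m - 1) for Poisson(m) crossovers: an even count of at least 2,
#' which leaves the population origin unchanged. Together with
#' [probStateChange()] and the zero-crossover probability e^-m this
#' partitions all outcomes: e^-m + even + change = 1.
#'
#' @inheritParams probStateChange
#' @return probabilities in [0, 1/2).
#' @export
probEvenRecomb <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("map length must be non-negative and finite")
  }
  expm1(-m)^2 / 2
}

#' Enumerate ancestry states for L markers
#'
#' All 2^L per-marker population-origin vectors, encoded as integer
#' bit-masks (marker j in bit j-1; 0 = population A, 1 = population B), in
#' ascending bit-mask order.
#'
#' @param L number of markers.
#' @param cap largest L allowed (default 10; hard maximum 15, beyond which
#'   the 2^L state space is refused rather than silently thrashed).
#' @return integer vector `0:(2^L - 1)`.
#' @examples
#' enumerateAncestryStates(3)
#' @export
enumerateAncestryStates <- function(L, cap = 10L) {
  L <- as.integer(L)
  cap <- min(as.integer(cap), 15L)
  if (L < 1L) stop("L must be at least 1")
  if (L > cap) {
    stop("L = ", L, " exceeds the marker cap of ", cap,
         " (hard maximum 15); analyze fewer markers per chromosome")
  }
  0:(2L^L - 1L)
}

#' Prior probability of a population ancestry state
#'
#' Probability Q(z | d, r) that a recombinant chromosome (one meiosis of an
#' A x B F1) carries population origins z = (z_1, ..., z_L) at the L
#' markers of `map`. The founder chromosome is drawn from A or B with
#' probability 1/2 each; each inter-marker interval then changes origin with
#' probability [probStateChange()] of its map length. The first interval
#' (5' end to marker 1) cancels out of the founder mixture, so Q does not
#' depend on it.
#'
#' @param state ancestry state: an integer bit-mask or a 0/1 vector of
#'   length L (0 = population A, 1 = population B).
#' @param map a [MarkerMap-class].
#' @return probability in [0, 1]; the 2^L values sum to 1.
#' @examples
#' m <- MarkerMap("chr1", c(1e6, 2e6), rates = 2)
#' ancestryStatePrior(c(0, 1), m)
#' @export
ancestryStatePrior <- function(state, map) {
  L <- nMarkers(map)
  z <- asBitmask(state, L)
  zbits <- hapToBits(z, L)
  # change probability on the 5' interval (has no net effect; kept for
  # fidelity to the two-term founder mixture)
  p1 <- probStateChange(mapPositions(map)[1L] / 1e6 * mapRates(map)[1L] / 100)
  pstar <- 1
  if (L > 1L) {
    pk <- probStateChange(mapLengths(map))
    chg <- abs(diff(zbits))
    pstar <- prod(ifelse(chg == 1L, pk, 1 - pk))
  }
  z1 <- zbits[1L]
  0.5 * p1^z1 * (1 - p1)^(1 - z1) * pstar +
    0.5 * p1^(1 - z1) * (1 - p1)^z1 * pstar
}

#' Prior probabilities of all ancestry states
#'
#' Vectorized companion to [ancestryStatePrior()]: Q(z | d, r) for every
#' state `0:(2^L - 1)` in ascending bit-mask order.
#'
#' @inheritParams ancestryStatePrior
#' @param cap largest L allowed (see [enumerateAncestryStates()]).
#' @return numeric vector of length 2^L summing to 1.
#' @export
ancestryStatePriors <- function(map, cap = 10L) {
  L <- nMarkers(map)
  states <- enumerateAncestryStates(L, cap = cap)
  if (L == 1L) return(setNames(c(0.5, 0.5), c("0", "1")))
  pk <- probStateChange(mapLengths(map))
  bits <- t(vapply(states, hapToBits, integer(L), L = L))
  chg <- abs(bits[, -1L, drop = FALSE] - bits[, -L, drop = FALSE])
  q <- 0.5 * apply(ifelse(chg == 1L, rep(pk, each = length(states)),
                          rep(1 - pk, each = length(states))), 1L, prod)
  setNames(q, vapply(states, hapToString, character(1), L = L))
}
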