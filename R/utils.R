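#' Convert between haplotype bit-masks and 0/1 strings
#'
#' Haplotypes are stored as integer bit-masks with marker j in bit j-1, so
#' the first character of the string form is marker 1.
#'
#' @param h integer bit-mask.
#' @param L number of markers.
#' @return `hapToString`: a string of `L` characters in 0/1;
#'   `stringToHap`: an integer bit-mask.
#' @examples
#' hapToString(5L, 4)   # "1010"
#' stringToHap("1010")  # 5
#' @export
hapToString <- function(h, L) {
  stopifnot(length(h) == 1L, h >= 0, h < 2^L)
  paste(bitwAnd(bitwShiftR(as.integer(h), 0:(L - 1L)), 1L), collapse = "")
}

#' @rdname hapToString
#' @param s character string of 0s and 1s, marker 1 first.
#' @export
stringToHap <- function(s) {
  bits <- as.integer(strsplit(s, "")[[1]])
  stopifnot(all(bits %in% 0:1))
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' @rdname hapToString
#' @param bits integer vector of 0/1 alleles, marker 1 first.
#' @export
bitsToHap <- function(bits) {
  stopifnot(all(bits %in% 0:1))
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' @rdname hapToString
#' @export
hapToBits <- function(h, L) {
  bitwAnd(bitwShiftR(as.integer(h), 0:(L - 1L)), 1L)
}

## Internal: accept either an integer bit-mask or a 0/1 vector of length L.
asBitmask <- function(x, L) {
  if (length(x) == L && L > 1L) return(bitsToHap(x))
  if (length(x) == 1L) {
    x <- as.integer(x)
    if (x < 0L || x > 2^L - 1) stop("bit-mask out of range for ", L, " markers")
    return(x)
  }
  stop("state/haplotype length does not match the marker count (", L, ")")
}

## Internal: genotype codes {0,1,2} from a pair of bit-mask vectors.
codesFromPair <- function(hapM, hapP, L) {
  hapToBits(hapM, L) + hapToBits(hapP, L)
}

#' Wright's island-model fixation index
#'
#' Under a symmetric island model with scaled migration rate M = 4*N0*m, the
#' expected fixation index between two populations is approximately
#' F_ST = 1 / (M + 1).
#'
#' @param M scaled migration rate(s), non-negative.
#' @return numeric vector of F_ST values.
#' @examples
#' wrightFst(c(0.1, 0.25, 1))
#' @export
wrightFst <- function(M) {
  stopifnot(all(is.finite(M)), all(M >= 0))
  1 / (M + 1)
}

#' Enumerate two-generation genealogical classes
#'
#' A non-inbred two-generation pedigree has four purebred founders, each from
#' population A or B: 16 assignments in all. Assignments that differ only by
#' swapping the two founders within a parent, or by swapping the two parents,
#' describe the same genealogy. Grouping the 16 assignments under these
#' symmetries yields exactly six classes: a (all four founders B), b (one
#' parent with founders A,A; the other A,B), c (founders A,A and B,B: F1),
#' d (all four founders A), e (founders B,B and A,B) and f (both parents
#' with founders A,B: F2).
#'
#' @return data.frame with one row per founder assignment (columns f1, f2 for
#'   the first parent's founders, f3, f4 for the second, "A"/"B"), the
#'   canonical orbit identifier, and the class label a-f.
#' @examples
#' g <- genealogicalClasses()
#' table(g$class)
#' @export
genealogicalClasses <- function() {
  pops <- c("A", "B")
  grid <- expand.grid(f1 = pops, f2 = pops, f3 = pops, f4 = pops,
                      stringsAsFactors = FALSE)
  canon <- function(f1, f2, f3, f4) {
    p1 <- paste(sort(c(f1, f2)), collapse = "")
    p2 <- paste(sort(c(f3, f4)), collapse = "")
    paste(sort(c(p1, p2)), collapse = "|")
  }
  grid$orbit <- mapply(canon, grid$f1, grid$f2, grid$f3, grid$f4)
  labels <- c("BB|BB" = "a", "AA|AB" = "b", "AA|BB" = "c",
              "AA|AA" = "d", "AB|BB" = "e", "AB|AB" = "f")
  grid$class <- unname(labels[grid$orbit])
  grid
}
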