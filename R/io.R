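## Readers and writers for the tabular formats, phased-VCF import, and
## marker selection.

#' Read and write marker map files
#'
#' Tab-separated with header `chrom marker_index pos_bp rate_cM_per_Mb`;
#' one row per marker, marker_index 1-based within chromosome; the rate on
#' a row applies to the interval ending at that marker.
#'
#' @param path file path.
#' @return `readMarkerMaps`: named list of [MarkerMap-class], one per
#'   chromosome, in file order.
#' @export
readMarkerMaps <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "marker_index", "pos_bp", "rate_cM_per_Mb")
  if (!all(need %in% names(df))) {
    stop("marker map file must have columns ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
                function(d) {
    d <- d[order(d$marker_index), ]
    MarkerMap(d$chrom[1L], d$pos_bp, d$rate_cM_per_Mb)
  })
  out
}

#' @rdname readMarkerMaps
#' @param maps list of [MarkerMap-class] (or a single map).
#' @export
writeMarkerMaps <- function(maps, path) {
  maps <- asChromList(maps, "maps")
  df <- do.call(rbind, lapply(maps, function(m) {
    data.frame(chrom = chromName(m),
               marker_index = seq_len(nMarkers(m)),
               pos_bp = mapPositions(m),
               rate_cM_per_Mb = mapRates(m))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write haplotype frequency tables
#'
#' Tab-separated with header
#' `chrom haplotype freq_A freq_B count_A count_B`; haplotypes are 0/1
#' strings ordered by marker index.
#'
#' @param path file path.
#' @return `readFreqTables`: named list of [HaplotypeFreqTable-class].
#' @export
readFreqTables <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(haplotype = "character"))
  need <- c("chrom", "haplotype", "freq_A", "freq_B", "count_A", "count_B")
  if (!all(need %in% names(df))) {
    stop("frequency table file must have columns ",
         paste(need, collapse = ", "))
  }
  lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
         function(d) {
    L <- nchar(d$haplotype[1L])
    HaplotypeFreqTable(d$chrom[1L], L,
                       support = vapply(d$haplotype, stringToHap,
                                        integer(1), USE.NAMES = FALSE),
                       freqA = d$freq_A, freqB = d$freq_B,
                       countA = d$count_A, countB = d$count_B,
                       sizeA = sum(d$count_A) / 2,
                       sizeB = sum(d$count_B) / 2)
  })
}

#' @rdname readFreqTables
#' @param tables list of [HaplotypeFreqTable-class] (or a single table).
#' @export
writeFreqTables <- function(tables, path) {
  tables <- asChromList(tables, "tables")
  df <- do.call(rbind, lapply(tables, function(tab) {
    data.frame(chrom = chromName(tab),
               haplotype = vapply(tab@support, hapToString, character(1),
                                  L = nMarkers(tab)),
               freq_A = tab@freqA, freq_B = tab@freqB,
               count_A = tab@countA, count_B = tab@countB)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write simulated haplotype tables
#'
#' Tab-separated with header `individual chrom copy haplotype true_class`;
#' `copy` is `M` or `P` and haplotypes are 0/1 strings.
#'
#' @param path file path.
#' @return `readHaplotypeTable`: list with `hapM`, `hapP` (individual x
#'   chromosome integer matrices), `classes`, `chroms`.
#' @export
readHaplotypeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(haplotype = "character"))
  chroms <- unique(df$chrom)
  ids <- unique(df$individual)
  grab <- function(copy) {
    d <- df[df$copy == copy, ]
    m <- matrix(0L, length(ids), length(chroms),
                dimnames = list(NULL, chroms))
    m[cbind(match(d$individual, ids), match(d$chrom, chroms))] <-
      vapply(d$haplotype, stringToHap, integer(1), USE.NAMES = FALSE)
    m
  }
  cls <- df$true_class[match(ids, df$individual)]
  list(hapM = grab("M"), hapP = grab("P"), classes = cls, ids = ids,
       chroms = chroms)
}

#' @rdname readHaplotypeTable
#' @param hapM,hapP integer matrices (individuals x chromosomes).
#' @param classes true class per individual (optional, `NA` allowed).
#' @param chroms chromosome names (default from columns).
#' @param Ls markers per chromosome.
#' @export
writeHaplotypeTable <- function(hapM, hapP, Ls, path, classes = NULL,
                                chroms = NULL) {
  hapM <- as.matrix(hapM); hapP <- as.matrix(hapP)
  N <- nrow(hapM); K <- ncol(hapM)
  if (is.null(chroms)) chroms <- colnames(hapM)
  if (is.null(chroms)) chroms <- paste0("chr", seq_len(K))
  if (is.null(classes)) classes <- rep(NA_character_, N)
  rows <- lapply(seq_len(K), function(i) {
    data.frame(individual = rep(seq_len(N), 2L),
               chrom = chroms[i],
               copy = rep(c("M", "P"), each = N),
               haplotype = c(vapply(hapM[, i], hapToString, character(1),
                                    L = Ls[i]),
                             vapply(hapP[, i], hapToString, character(1),
                                    L = Ls[i])),
               true_class = rep(classes, 2L))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$individual, df$chrom, df$copy), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a posterior table
#'
#' Tab-separated with header `individual P_a..P_f map_class
#' log10_lik_a..log10_lik_f method`, the schema produced by
#' [classifyIndividuals()] and [classifyComposite()].
#'
#' @param table classification data.frame.
#' @param path file path.
#' @export
writePosteriors <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes (or genotype codes) from a VCF
#'
#' Reads biallelic SNP records and returns, per chromosome, either two
#' haplotype bit-vectors per sample (phased mode, requiring `|`-separated
#' GT fields) or genotype codes 0/1/2 (unphased mode). Sites that are
#' multiallelic, non-SNP, or have missing (or, in phased mode, unphased)
#' genotypes in the requested samples are dropped with a message.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param samples sample names to extract (default: all).
#' @param phased if `TRUE` (default) require phased GT and return
#'   haplotypes; if `FALSE` return genotype codes.
#' @param chrom restrict to one chromosome/scaffold (default: all).
#' @return named list per chromosome, each with `positions` (bp) and either
#'   `haplotypes` (2N x L 0/1 matrix, rows `sample.0`/`sample.1`) or
#'   `codes` (N x L matrix).
#' @export
readPhasedVcf <- function(path, samples = NULL, phased = TRUE,
                          chrom = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt[, -1L, drop = FALSE]
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(gt))
    if (length(miss) > 0L) stop("samples not in VCF: ",
                                paste(miss, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  # GT is the first colon-separated field
  gtOnly <- sub(":.*$", "", gt)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt)
  if (any(!biallelic)) {
    message(sum(!biallelic), " multiallelic/non-SNP record(s) skipped")
  }
  okGt <- matrix(grepl(paste0("^[01]", if (phased) "\\|" else "[|/]",
                              "[01]$"), gtOnly), nrow = nrow(gtOnly))
  keep <- biallelic & rowSums(!okGt) == 0L
  if (!any(keep)) stop("no usable ", if (phased) "phased " else "",
                       "biallelic sites found")
  dropped <- sum(biallelic & !keep)
  if (dropped > 0L) {
    message(dropped, " site(s) dropped for missing/unsuitable genotypes")
  }
  fix <- fix[keep, , drop = FALSE]
  gtOnly <- gtOnly[keep, , drop = FALSE]
  chroms <- fix[, "CHROM"]
  if (!is.null(chrom)) {
    sel <- chroms == chrom
    fix <- fix[sel, , drop = FALSE]
    gtOnly <- gtOnly[sel, , drop = FALSE]
    chroms <- chroms[sel]
  }
  out <- list()
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    pos <- as.numeric(fix[sel, "POS"])
    g <- gtOnly[sel, , drop = FALSE]
    if (phased) {
      a0 <- matrix(as.integer(substr(g, 1L, 1L)), nrow = nrow(g))
      a1 <- matrix(as.integer(substr(g, 3L, 3L)), nrow = nrow(g))
      haps <- matrix(0L, 2L * ncol(g), nrow(g))
      haps[seq(1L, by = 2L, length.out = ncol(g)), ] <- t(a0)
      haps[seq(2L, by = 2L, length.out = ncol(g)), ] <- t(a1)
      rownames(haps) <- paste(rep(colnames(g), each = 2L), 0:1, sep = ".")
      out[[ch]] <- list(positions = pos, haplotypes = haps)
    } else {
      codes <- t(matrix(as.integer(substr(g, 1L, 1L)) +
                          as.integer(substr(g, 3L, 3L)), nrow = nrow(g)))
      rownames(codes) <- colnames(g)
      out[[ch]] <- list(positions = pos, codes = codes)
    }
  }
  out
}

#' Select approximately equidistant markers
#'
#' Chooses L markers whose positions are closest to L equally spaced target
#' positions over the requested span (or the full candidate range for
#' `span = "max"`). Each target maps to the nearest unused candidate; on a
#' collision the next-nearest unused site is taken. For L = 1 the site
#' nearest the span midpoint is chosen.
#'
#' @param positions candidate site positions (bp), increasing.
#' @param L number of markers to choose.
#' @param span `"max"` or a physical span in bp, centered on the candidate
#'   range.
#' @return strictly increasing integer indices into `positions`.
#' @export
selectMarkers <- function(positions, L, span = "max") {
  n <- length(positions)
  if (n < L) stop("only ", n, " candidate sites for ", L, " markers")
  if (identical(span, "max")) {
    lo <- positions[1L]; hi <- positions[n]
  } else {
    mid <- (positions[1L] + positions[n]) / 2
    lo <- mid - span / 2; hi <- mid + span / 2
  }
  targets <- if (L == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = L)
  chosen <- integer(0)
  for (tg in targets) {
    ord <- order(abs(positions - tg))
    pick <- ord[!(ord %in% chosen)][1L]
    chosen <- c(chosen, pick)
  }
  sort(chosen)
}
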