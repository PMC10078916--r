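## Performance metrics over labelled posterior tables: calibration, power
## at a posterior threshold, and one-vs-rest ROC analysis.

## Internal: extract the N x 6 posterior matrix from a classification
## data.frame (as returned by classifyIndividuals / classifyComposite) or
## pass a plain matrix through.
posteriorMatrix <- function(table) {
  if (is.data.frame(table)) {
    cols <- paste0("P_", CLASS_LABELS)
    if (!all(cols %in% names(table))) {
      stop("expected posterior columns ", paste(cols, collapse = ", "))
    }
    m <- as.matrix(table[, cols])
    colnames(m) <- CLASS_LABELS
    return(m)
  }
  m <- as.matrix(table)
  if (ncol(m) != 6L) stop("posterior matrix must have 6 columns")
  colnames(m) <- CLASS_LABELS
  m
}

#' Calibration of posterior probabilities
#'
#' Bins every (individual, class) posterior probability into intervals on
#' [0, 1] and reports, per class and bin, the fraction of entries whose true
#' class is that class. A calibrated method puts the per-bin proportion on
#' the identity line against the bin midpoint.
#'
#' @param table classification data.frame (columns `P_a`..`P_f`) or an
#'   N x 6 posterior matrix.
#' @param truth true classes, `"a"`-`"f"`, length N.
#' @param bins number of equal-width bins (default 20), or a vector of
#'   breakpoints partitioning [0, 1] (right-closed; the first bin includes
#'   0).
#' @param pooled if `TRUE`, additionally return rows pooling all classes
#'   (`class = "all"`).
#' @return data.frame with columns `class`, `midpoint`, `meanPosterior`
#'   (the mean stated posterior within the bin, the exact identity-line
#'   reference; `NA` for empty bins), `proportion` (`NA` for empty bins)
#'   and `count`.
#' @export
calibrationTable <- function(table, truth, bins = 20L, pooled = TRUE) {
  post <- posteriorMatrix(table)
  stopifnot(length(truth) == nrow(post), all(truth %in% CLASS_LABELS))
  breaks <- if (length(bins) == 1L) seq(0, 1, length.out = bins + 1L)
            else as.numeric(bins)
  if (breaks[1L] != 0 || breaks[length(breaks)] != 1 ||
      any(diff(breaks) <= 0)) {
    stop("bins must partition [0, 1] with increasing breakpoints")
  }
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  nb <- length(mids)
  binUp <- function(label, p, hit) {
    idx <- findInterval(p, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    cnt <- tabulate(idx, nbins = nb)
    ok <- tabulate(idx[hit], nbins = nb)
    mp <- rep(NA_real_, nb)
    s <- tapply(p, factor(idx, levels = seq_len(nb)), mean)
    mp[!is.na(s)] <- s[!is.na(s)]
    data.frame(class = label, midpoint = mids, meanPosterior = mp,
               proportion = ifelse(cnt > 0, ok / cnt, NA_real_),
               count = cnt)
  }
  out <- do.call(rbind, lapply(CLASS_LABELS, function(g)
    binUp(g, post[, g], truth == g)))
  if (pooled) {
    out <- rbind(out, binUp("all", as.vector(post),
                            as.vector(outer(truth, CLASS_LABELS, "=="))))
  }
  rownames(out) <- NULL
  out
}

#' Power at a posterior threshold
#'
#' Per class, the fraction of individuals of that true class whose
#' posterior probability for it exceeds the threshold. An `argmax` column
#' reports plain highest-posterior accuracy as an auxiliary summary.
#'
#' @inheritParams calibrationTable
#' @param t posterior threshold in [0, 1] (default 0.9).
#' @return data.frame with columns `class`, `n`, `power`, `argmax`.
#' @export
powerAtThreshold <- function(table, truth, t = 0.9) {
  stopifnot(t >= 0, t <= 1)
  post <- posteriorMatrix(table)
  stopifnot(length(truth) == nrow(post), all(truth %in% CLASS_LABELS))
  amax <- CLASS_LABELS[max.col(post, ties.method = "first")]
  out <- lapply(CLASS_LABELS, function(g) {
    sel <- truth == g
    data.frame(class = g, n = sum(sel),
               power = if (any(sel)) mean(post[sel, g] > t) else NA_real_,
               argmax = if (any(sel)) mean(amax[sel] == g) else NA_real_)
  })
  do.call(rbind, out)
}

#' One-vs-rest ROC points for a genealogical class
#'
#' For each threshold t: power = P(posterior_g > t | truth = g) and type-I
#' error = P(posterior_g > t | truth != g).
#'
#' @inheritParams calibrationTable
#' @param g class, one of `"a"`-`"f"`.
#' @param thresholds thresholds in [0, 1].
#' @return data.frame with columns `threshold`, `typeI`, `power`, both
#'   coordinates non-increasing in the threshold.
#' @export
rocPoints <- function(table, truth, g,
                      thresholds = seq(0, 1, by = 0.01)) {
  g <- match.arg(g, CLASS_LABELS)
  post <- posteriorMatrix(table)
  stopifnot(length(truth) == nrow(post), all(truth %in% CLASS_LABELS))
  if (!any(truth == g)) stop("no individuals with true class ", g)
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  p <- post[, g]
  pos <- truth == g
  data.frame(threshold = thresholds,
             typeI = vapply(thresholds, function(t) mean(p[!pos] > t),
                            numeric(1)),
             power = vapply(thresholds, function(t) mean(p[pos] > t),
                            numeric(1)))
}

#' Area under the one-vs-rest ROC curve
#'
#' Computed rank-based (Mann-Whitney), which equals the area under the
#' exact ROC curve traced over all thresholds, with ties handled by the
#' usual 1/2 convention.
#'
#' @inheritParams rocPoints
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(table, truth, g) {
  g <- match.arg(g, CLASS_LABELS)
  post <- posteriorMatrix(table)
  stopifnot(length(truth) == nrow(post), all(truth %in% CLASS_LABELS))
  p <- post[, g]
  pos <- truth == g
  if (!any(pos) || all(pos)) stop("need both positive and negative truths")
  r <- rank(p)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
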