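#' Mean composition of a peptide set
#'
#' Encodes every peptide under the scheme and averages featurewise; the
#' per-feature standard deviation is reported alongside (error bars for
#' composition plots). For AAC/DPC the mean vector sums to 100 because
#' each per-peptide encoding does.
#'
#' @param peps peptide set.
#' @param scheme `"AAC"` or `"DPC"`.
#' @return data.frame with `feature`, `mean`, `sd`.
#' @export
mean_composition <- function(peps, scheme = c("AAC", "DPC")) {
  scheme <- match.arg(scheme)
  X <- encode_peptides(peps, scheme)
  sds <- if (nrow(X) == 1L) rep(0, ncol(X)) else apply(X, 2L, stats::sd)
  data.frame(feature = colnames(X), mean = colMeans(X),
             sd = sds, row.names = NULL)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (a thin wrapper over
#' [stats::t.test()]).
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return named list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate samples: both variances are zero")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Compare residue or dipeptide composition between two peptide sets
#'
#' Per feature, the per-peptide composition values of the two sets are the
#' two samples of a Welch t-test. Rows are sorted by p-value. Features
#' with zero variance in both sets (typically dipeptides absent from both)
#' are reported with `p = 1`, `t = 0` and `degenerate = TRUE` rather than
#' dropped. Raw p-values are reported (no multiple-testing correction);
#' an optional Benjamini-Hochberg column can be added.
#'
#' @param pos,neg peptide sets.
#' @param scheme `"AAC"` or `"DPC"`.
#' @param adjust add a BH-adjusted p-value column.
#' @return data.frame with `feature`, `mean_pos`, `mean_neg`, `diff`, `t`,
#'   `df`, `p`, `degenerate` (and `p_adj` when `adjust = TRUE`), sorted by
#'   `p`.
#' @export
compare_compositions <- function(pos, neg, scheme = c("AAC", "DPC"),
                                 adjust = FALSE) {
  scheme <- match.arg(scheme)
  Xp <- encode_peptides(pos, scheme)
  Xn <- encode_peptides(neg, scheme)
  rows <- lapply(colnames(Xp), function(f) {
    x <- Xp[, f]; y <- Xn[, f]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      data.frame(feature = f, mean_pos = mean(x), mean_neg = mean(y),
                 diff = mean(x) - mean(y), t = 0, df = NA_real_, p = 1,
                 degenerate = TRUE)
    } else {
      w <- welch_t(x, y)
      data.frame(feature = f, mean_pos = mean(x), mean_neg = mean(y),
                 diff = mean(x) - mean(y), t = w$t, df = w$df, p = w$p,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length distribution of a peptide set
#'
#' Percentage of peptides per length bin; bins are defined by their edges
#' and are inclusive on both ends of each `[lo, hi]` interval. Percentages
#' sum to 100 over peptides falling inside the bins.
#'
#' @param peps peptide set.
#' @param bins 2-column matrix or list of `c(lo, hi)` length intervals;
#'   default 4-10, 11-15, 16-20, 21-30, 31-50.
#' @return data.frame with `bin`, `count`, `percent`.
#' @export
length_distribution <- function(peps,
                                bins = list(c(4, 10), c(11, 15), c(16, 20),
                                            c(21, 30), c(31, 50))) {
  if (!nrow(peps)) stop("empty peptide set")
  if (is.matrix(bins)) bins <- split(bins, row(bins))
  L <- nchar(peps$seq)
  counts <- vapply(bins, function(b) sum(L >= b[1] & L <= b[2]), numeric(1))
  total <- sum(counts)
  if (total == 0) stop("no peptide falls inside the given bins")
  data.frame(bin = vapply(bins, function(b) paste0(b[1], "-", b[2]),
                          character(1)),
             count = counts, percent = 100 * counts / total)
}

#' Positional residue preference between two fixed-length sets
#'
#' For every position and residue, the frequency difference between the
#' positive and negative sets together with a two-sided two-proportion
#' z-test p-value (with continuity correction, via [stats::prop.test()]).
#' This is the numeric substrate of a two-sample sequence logo.
#'
#' @param pos,neg peptide sets whose sequences all share one length.
#' @return data.frame with `position`, `residue`, `freq_pos`, `freq_neg`,
#'   `diff`, `p`.
#' @export
position_preference <- function(pos, neg) {
  Lp <- unique(nchar(pos$seq)); Ln <- unique(nchar(neg$seq))
  if (length(Lp) != 1L || length(Ln) != 1L || Lp != Ln)
    stop("position preference needs fixed-length sets of a common length")
  L <- Lp
  np <- nrow(pos); nn <- nrow(neg)
  mp <- do.call(rbind, strsplit(pos$seq, "", fixed = TRUE))
  mn <- do.call(rbind, strsplit(neg$seq, "", fixed = TRUE))
  rows <- lapply(seq_len(L), function(j) {
    cp <- tabulate(factor(mp[, j], levels = AA20), nbins = 20L)
    cn <- tabulate(factor(mn[, j], levels = AA20), nbins = 20L)
    p <- vapply(seq_len(20L), function(r) {
      if (cp[r] + cn[r] == 0L) return(1)
      suppressWarnings(
        stats::prop.test(c(cp[r], cn[r]), c(np, nn), correct = TRUE)$p.value)
    }, numeric(1))
    data.frame(position = j, residue = AA20,
               freq_pos = cp / np, freq_neg = cn / nn,
               diff = cp / np - cn / nn, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
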