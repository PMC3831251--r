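#' Scan an antigen with a sliding window
#'
#' Scores every window of the given length (at the given stride) with a
#' trained per-class model and reports the windows reaching the decision
#' threshold. Coordinates are 1-based inclusive; a stride-1 scan of a
#' length-L antigen scores exactly `L - window + 1` windows.
#'
#' @param antigen antigen sequence (single string, or a one-row peptide
#'   set).
#' @param bundle `model_bundle`.
#' @param window window length (default 20, the fixed-length model width).
#' @param stride step between window starts.
#' @param threshold overrides the bundle's stored threshold.
#' @param full_profile if `TRUE` return every scored window, not only the
#'   hits.
#' @return data.frame of scan hits: `antigen`, `start`, `end`, `window`,
#'   `class`, `score`, `threshold`. With `full_profile = TRUE` the full
#'   profile is in attribute `"profile"` as well.
#' @export
scan_windows <- function(antigen, bundle, window = 20L, stride = 1L,
                         threshold = NULL, full_profile = FALSE) {
  ag <- as_antigen(antigen)
  L <- nchar(ag$seq)
  if (L < window)
    stop("antigen (", L, " aa) shorter than the scan window (", window, ")")
  thr <- threshold %||% bundle$threshold
  starts <- seq.int(1L, L - window + 1L, by = stride)
  wins <- substring(ag$seq, starts, starts + window - 1L)
  sc <- unname(score_peptides(bundle, wins))
  prof <- data.frame(antigen = ag$id, start = starts,
                     end = starts + window - 1L, window = wins,
                     class = bundle$class_name, score = sc, threshold = thr)
  hits <- prof[prof$score >= thr, , drop = FALSE]
  rownames(hits) <- NULL
  if (full_profile) attr(hits, "profile") <- prof
  hits
}

#' Multi-window antigen scan
#'
#' Variable-length scanning: runs [scan_windows()] over a range of window
#' lengths with a model trained on variable-length data and pools the hits
#' (ranked by score).
#'
#' @inheritParams scan_windows
#' @param windows integer vector of window lengths (default 8:20).
#' @return pooled hit data.frame ranked by decreasing score.
#' @export
scan_windows_multi <- function(antigen, bundle, windows = 8:20, stride = 1L,
                               threshold = NULL) {
  ag <- as_antigen(antigen)
  windows <- windows[windows <= nchar(ag$seq)]
  if (!length(windows)) stop("antigen shorter than every requested window")
  hits <- do.call(rbind, lapply(windows, function(w)
    scan_windows(stats::setNames(ag$seq, ag$id), bundle, window = w,
                 stride = stride, threshold = threshold)))
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map known epitopes onto an antigen by exact substring match
#'
#' Reports every exact occurrence of every known epitope in the antigen,
#' including overlapping occurrences, with 1-based inclusive coordinates
#' and the epitope's class label.
#'
#' @param antigen antigen sequence.
#' @param known labeled peptide set of experimentally verified epitopes.
#' @return data.frame with `antigen`, `start`, `end`, `window`, `class`,
#'   `epitope_id`.
#' @export
map_exact_epitopes <- function(antigen, known) {
  ag <- as_antigen(antigen)
  subject <- Biostrings::AAString(ag$seq)
  rows <- lapply(seq_len(nrow(known)), function(i) {
    m <- Biostrings::matchPattern(known$seq[i], subject)
    if (!length(m)) return(NULL)
    data.frame(antigen = ag$id, start = Biostrings::start(m),
               end = Biostrings::end(m), window = known$seq[i],
               class = known$label[i], epitope_id = known$id[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(antigen = character(), start = integer(),
                      end = integer(), window = character(),
                      class = character(), epitope_id = character())
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

#' Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment score under affine gap penalties, computed with
#' a match/mismatch substitution scheme: a gap of length k is penalised by
#' `|gap_open| + k * |gap_extend|`. The score is never negative (the empty
#' alignment scores 0) and is symmetric in its two sequences.
#'
#' @param a,b peptide sequences (single strings).
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap-opening penalty (<= 0, charged once per gap).
#' @param gap_extend gap-extension penalty (<= 0, charged per gap residue).
#' @return list with `score` and the 1-based inclusive aligned region
#'   coordinates `a_start`, `a_end`, `b_start`, `b_end` (`NA` when the
#'   optimal local alignment is empty).
#' @export
smith_waterman <- function(a, b, match = 2, mismatch = -1,
                           gap_open = -10, gap_extend = -1) {
  stopifnot(nzchar(a), nzchar(b), match > 0, mismatch <= 0,
            gap_open <= 0, gap_extend <= 0)
  al <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), substitutionMatrix = sw_submat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap_extend, type = "local")
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = max(0, sc),
                a_start = NA_integer_, a_end = NA_integer_,
                b_start = NA_integer_, b_end = NA_integer_))
  }
  p <- Biostrings::pattern(al); s <- Biostrings::subject(al)
  list(score = sc,
       a_start = Biostrings::start(p), a_end = Biostrings::end(p),
       b_start = Biostrings::start(s), b_end = Biostrings::end(s))
}

# Identity-style substitution matrix over the alphabet (+ pad, which
# mismatches everything including itself).
sw_submat <- function(match, mismatch) {
  alpha <- c(AA20, PAD)
  m <- matrix(mismatch, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- match
  m[PAD, PAD] <- mismatch
  m
}

#' Similarity search of known epitopes against an antigen
#'
#' Aligns every known epitope to the antigen with [smith_waterman()] and
#' returns the hits with score at or above `min_score`, ranked by score
#' (ties by epitope id).
#'
#' @param antigen antigen sequence.
#' @param known labeled peptide set of known epitopes.
#' @param min_score minimum alignment score to report.
#' @param match,mismatch,gap_open,gap_extend scoring scheme, see
#'   [smith_waterman()].
#' @return data.frame with `antigen`, `epitope_id`, `class`, `score`,
#'   `start`, `end` (antigen coordinates), `epi_start`, `epi_end`.
#' @export
similarity_search <- function(antigen, known, min_score = 0,
                              match = 2, mismatch = -1,
                              gap_open = -10, gap_extend = -1) {
  if (!nrow(known)) stop("empty set of known epitopes")
  ag <- as_antigen(antigen)
  rows <- lapply(seq_len(nrow(known)), function(i) {
    al <- smith_waterman(known$seq[i], ag$seq, match, mismatch,
                         gap_open, gap_extend)
    data.frame(antigen = ag$id, epitope_id = known$id[i],
               class = known$label[i], score = al$score,
               start = al$b_start, end = al$b_end,
               epi_start = al$a_start, epi_end = al$a_end)
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(-out$score, out$epitope_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Accept a raw string or a one-row peptide set as an antigen.
as_antigen <- function(antigen) {
  if (is.data.frame(antigen)) {
    stopifnot(nrow(antigen) == 1L)
    list(id = antigen$id, seq = antigen$seq)
  } else {
    stopifnot(is.character(antigen), length(antigen) == 1L)
    s <- toupper(antigen)
    if (!valid_sequence(s)) stop("antigen has out-of-alphabet characters")
    list(id = names(antigen) %||% "antigen", seq = s)
  }
}
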