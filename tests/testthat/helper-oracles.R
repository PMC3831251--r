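# Independent brute-force oracles and fixture builders used across the
# suite. Everything here is deliberately naive and kept separate from the
# package implementation paths it checks.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DIPS <- as.vector(t(outer(AA, AA, paste0)))

random_peptides <- function(n, lengths = 8:25, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    L <- if (length(lengths) == 1L) lengths else sample(lengths, 1)
    paste(sample(AA, L, replace = TRUE), collapse = "")
  }, character(1)))
}

# Letter-counting oracle for amino-acid composition (percent).
oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ch <- ch[ch != "X"]
  100 * vapply(AA, function(a) sum(ch == a), numeric(1)) / length(ch)
}

# Window-enumeration oracle for dipeptide composition (percent).
oracle_dpc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  wins <- character(0)
  for (i in seq_len(length(ch) - 1)) {
    if (ch[i] != "X" && ch[i + 1] != "X")
      wins <- c(wins, paste0(ch[i], ch[i + 1]))
  }
  100 * vapply(DIPS, function(d) sum(wins == d), numeric(1)) / length(wins)
}

# Pair-counting (Mann-Whitney) oracle for the AUC: concordant positive x
# negative pairs plus half the ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Full Gotoh dynamic-programming oracle for local alignment with affine
# gaps: a gap of length k costs |gap_open| + k * |gap_extend|.
oracle_sw <- function(a, b, match = 2, mismatch = -1,
                      gap_open = -10, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- -gap_open; ext <- -gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      sub <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Direct plug-in of the four metric equations, coded independently.
oracle_metrics <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(Sens = 100 * tp / (tp + fn),
    Spec = 100 * tn / (tn + fp),
    Acc = 100 * (tp + tn) / (tp + fp + tn + fn),
    MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Tiny two-cluster dataset that is linearly separable in residue
# composition: positives over {A, D, E}, negatives over {K, L, M}.
separable_dataset <- function(n_per_class = 40, seed = 1) {
  withr::with_seed(seed, {
    pos <- vapply(seq_len(n_per_class), function(i)
      paste(sample(c("A", "D", "E"), 12, replace = TRUE), collapse = ""),
      character(1))
    neg <- vapply(seq_len(n_per_class), function(i)
      paste(sample(c("K", "L", "M"), 12, replace = TRUE), collapse = ""),
      character(1))
    build_one_vs_rest(list(IgE = peptide_set(pos, label = "IgE"),
                           nonBCE = peptide_set(neg, label = "nonBCE")),
                      "IgE")
  })
}
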