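#' Amino-acid composition (AAC)
#'
#' Percent frequency of each of the 20 residues, a fixed vector of 20 per
#' peptide. The pad symbol `X` contributes to no channel and is excluded
#' from the length denominator, so values always sum to 100.
#'
#' @param seqs character vector of peptide sequences (pad `X` allowed).
#' @return numeric matrix, one row per peptide, 20 columns named `A..Y`.
#' @export
encode_aac <- function(seqs) {
  seqs <- as_seqs(seqs)
  out <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch <- ch[ch != PAD]
    if (!length(ch)) stop("sequence is empty after pad exclusion")
    100 * tabulate(factor(ch, levels = AA20), nbins = 20L) / length(ch)
  }, numeric(20L)))
  dimnames(out) <- list(names(seqs), AA20)
  out
}

#' Dipeptide composition (DPC)
#'
#' Percent frequency of each of the 400 ordered residue pairs over all
#' overlapping windows, giving a fixed pattern length of 400:
#' `100 * count(dipeptide) / count(all windows)`. Windows containing the
#' pad symbol are skipped and excluded from the denominator.
#'
#' @inheritParams encode_aac
#' @return numeric matrix, 400 columns in lexicographic dipeptide order.
#' @export
encode_dpc <- function(seqs) {
  seqs <- as_seqs(seqs)
  out <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 2L) stop("dipeptide composition needs length >= 2")
    a <- ch[-n]; b <- ch[-1L]
    keep <- a != PAD & b != PAD
    if (!sum(keep)) stop("no pad-free dipeptide window in sequence")
    d <- paste0(a[keep], b[keep])
    100 * tabulate(factor(d, levels = DIPEPTIDES), nbins = 400L) / sum(keep)
  }, numeric(400L)))
  dimnames(out) <- list(names(seqs), DIPEPTIDES)
  out
}

#' Binary profile encoding (BIN)
#'
#' Position-wise one-hot encoding of fixed-length peptides: each position
#' becomes a block of 20 indicator channels, so a window of 20 residues
#' gives a 400-dimensional 0/1 vector. Pad positions yield all-zero blocks.
#'
#' @inheritParams encode_aac
#' @param window required peptide length (default 20).
#' @return numeric 0/1 matrix with `20 * window` columns named
#'   `p<position>.<residue>`.
#' @export
encode_binary <- function(seqs, window = 20L) {
  seqs <- as_seqs(seqs)
  if (any(nchar(seqs) != window))
    stop("binary profile requires every sequence to have length ", window)
  dim <- 20L * window
  out <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    v <- numeric(dim)
    idx <- match(ch, AA20)          # NA for pad -> block stays zero
    hit <- !is.na(idx)
    v[(which(hit) - 1L) * 20L + idx[hit]] <- 1
    v
  }, numeric(dim)))
  cols <- paste0("p", rep(sprintf("%02d", seq_len(window)), each = 20L),
                 ".", rep(AA20, window))
  dimnames(out) <- list(names(seqs), cols)
  out
}

#' Build an amino-acid-pair (AAP) propensity scale
#'
#' For each ordered dipeptide the scale holds the smoothed log-ratio of its
#' pooled relative frequency in the positive versus the negative peptides,
#' `log((f+ + eps) / (f- + eps))`, linearly rescaled to `[-1, 1]` across the
#' 400 entries. The smoothing constant is `1 / (dipeptide count of the
#' smaller pool)`, so pairs absent from both pools get a raw propensity of
#' exactly 0.
#'
#' @param pos,neg peptide sets (or character vectors) for the two pools.
#' @return object of class `aap_scale` with elements `scaled` (named
#'   400-vector in `[-1, 1]`), `raw` and `eps`.
#' @export
build_aap_scale <- function(pos, neg) {
  fp <- pooled_dip_freq(pos)
  fn <- pooled_dip_freq(neg)
  eps <- 1 / min(attr(fp, "total"), attr(fn, "total"))
  raw <- log((fp + eps) / (fn + eps))
  attr(raw, "total") <- NULL
  rng <- range(raw)
  scaled <- if (diff(rng) == 0) {
    raw * 0
  } else {
    2 * (raw - rng[1]) / diff(rng) - 1
  }
  structure(list(scaled = scaled, raw = raw, eps = eps), class = "aap_scale")
}

# Pooled relative dipeptide frequency over a set of peptides; attribute
# "total" carries the pooled window count (used for the smoothing constant).
pooled_dip_freq <- function(peps) {
  seqs <- as_seqs(peps)
  if (!length(seqs)) stop("peptide pool is empty")
  counts <- numeric(400L)
  total <- 0L
  for (s in seqs) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 2L) next
    a <- ch[-n]; b <- ch[-1L]
    keep <- a != PAD & b != PAD
    if (!sum(keep)) next
    d <- paste0(a[keep], b[keep])
    counts <- counts + tabulate(factor(d, levels = DIPEPTIDES), nbins = 400L)
    total <- total + sum(keep)
  }
  if (total == 0L) stop("no dipeptide windows in pool")
  structure(stats::setNames(counts / total, DIPEPTIDES), total = total)
}

#' Amino-acid-pair propensity encoding (AAP)
#'
#' Dipeptide composition weighted elementwise by a fitted propensity scale:
#' `value(d) = DPC(d) * scale(d)`. The scale must be built on training data
#' only (see [build_aap_scale()]); the vector size stays 400.
#'
#' @inheritParams encode_aac
#' @param scale an `aap_scale` from [build_aap_scale()].
#' @return numeric matrix with 400 columns.
#' @export
encode_aap <- function(seqs, scale) {
  stopifnot(inherits(scale, "aap_scale"))
  dpc <- encode_dpc(seqs)
  sweep(dpc, 2L, scale$scaled[colnames(dpc)], `*`)
}

#' Physico-chemical property encoding (PCP)
#'
#' One value per property: the mean per-residue property value over the
#' peptide (pad positions excluded). The default table ships ten commonly
#' used properties (see [pcp_table()]).
#'
#' @inheritParams encode_aac
#' @param table residue-by-property numeric matrix; default [pcp_table()].
#' @return numeric matrix, one column per property.
#' @export
encode_pcp <- function(seqs, table = pcp_table()) {
  seqs <- as_seqs(seqs)
  stopifnot(is.matrix(table), all(AA20 %in% rownames(table)))
  p <- ncol(table)
  out <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch <- ch[ch != PAD]
    if (!length(ch)) stop("sequence is empty after pad exclusion")
    colMeans(table[ch, , drop = FALSE])
  }, numeric(p)))
  dimnames(out) <- list(names(seqs), colnames(table))
  out
}

#' Composition-transition-distribution encoding (CTD)
#'
#' For each physico-chemical property the peptide is mapped to a string over
#' three group symbols, then summarised by 21 features: 3 composition
#' percentages, 3 transition percentages (unordered adjacent symbol pairs
#' over the L-1 adjacencies) and, per symbol, the sequence positions (as
#' percent of L) of its 1st, 25%, 50%, 75% and 100% occurrences
#' (0 for absent symbols; quantile occurrence index `ceiling(q * count)`).
#' Pad positions are dropped before mapping.
#'
#' @inheritParams encode_aac
#' @param groups 3-group residue partitions per property; default
#'   [ctd_groups()] (seven standard properties, 147 features).
#' @return numeric matrix with `21 * length(groups)` columns named
#'   `<property>.<block>`.
#' @export
encode_ctd <- function(seqs, groups = ctd_groups()) {
  seqs <- as_seqs(seqs)
  p <- length(groups)
  blocks <- c(paste0("C", 1:3),
              c("T12", "T13", "T23"),
              paste0("D", rep(1:3, each = 5L), ".",
                     rep(c("first", "q25", "q50", "q75", "q100"), 3L)))
  cols <- paste0(rep(names(groups), each = 21L), ".", rep(blocks, p))
  out <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch <- ch[ch != PAD]
    if (length(ch) < 2L) stop("CTD needs length >= 2 after pad exclusion")
    unlist(lapply(groups, function(g) ctd_one_property(ch, g)),
           use.names = FALSE)
  }, numeric(21L * p)))
  dimnames(out) <- list(names(seqs), cols)
  out
}

# 21 CTD features for one residue chain under one 3-group partition.
ctd_one_property <- function(ch, grp) {
  sym <- grp[ch]
  L <- length(sym)
  comp <- 100 * tabulate(sym, nbins = 3L) / L
  a <- sym[-L]; b <- sym[-1L]
  lo <- pmin(a, b); hi <- pmax(a, b)
  mixed <- lo != hi
  trans <- vapply(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), function(pr) {
    100 * sum(mixed & lo == pr[1] & hi == pr[2]) / (L - 1L)
  }, numeric(1))
  dist <- unlist(lapply(1:3, function(s) {
    pos <- which(sym == s)
    cnt <- length(pos)
    if (!cnt) return(numeric(5L))
    idx <- pmax(1L, ceiling(c(0, .25, .5, .75, 1) * cnt))
    100 * pos[idx] / L
  }), use.names = FALSE)
  c(comp, trans, dist)
}

#' Encode peptides under a named scheme
#'
#' Dispatcher over the six encoders; the `artifacts` list carries any fitted
#' components a scheme needs (the AAP propensity scale).
#'
#' @inheritParams encode_aac
#' @param scheme one of `"AAC"`, `"DPC"`, `"BIN"`, `"AAP"`, `"PCP"`, `"CTD"`.
#' @param artifacts list; `aap_scale` is required for `scheme = "AAP"`.
#' @param window binary-profile window length.
#' @return numeric feature matrix, one row per peptide.
#' @export
encode_peptides <- function(seqs, scheme, artifacts = list(), window = 20L) {
  scheme <- toupper(scheme)
  switch(scheme,
    AAC = encode_aac(seqs),
    DPC = encode_dpc(seqs),
    BIN = encode_binary(seqs, window = window),
    AAP = {
      if (is.null(artifacts$aap_scale))
        stop("scheme 'AAP' needs artifacts$aap_scale (see build_aap_scale)")
      encode_aap(seqs, artifacts$aap_scale)
    },
    PCP = encode_pcp(seqs, table = artifacts$pcp_table %||% pcp_table()),
    CTD = encode_ctd(seqs, groups = artifacts$ctd_groups %||% ctd_groups()),
    stop("unknown encoding scheme: ", scheme)
  )
}

#' Built-in physico-chemical property table
#'
#' Ten per-residue properties (version 1, frozen): Kyte-Doolittle
#' hydrophobicity, Hopp-Woods hydrophilicity, Zimmerman bulkiness,
#' hydrogen-bond donor count, a steric-hindrance parameter, Fauchere
#' amphiphilicity, net charge at pH 7, isoelectric point, residue volume and
#' Grantham polarity. Users may pass their own matrix of the same shape to
#' [encode_pcp()].
#'
#' @return 20 x 10 numeric matrix, rows named by residue.
#' @export
pcp_table <- function() {
  path <- system.file("extdata", "pcp_properties.tsv", package = "epiclass")
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  stopifnot(identical(sort(rownames(m)), AA20))
  m[AA20, , drop = FALSE]
}

#' Built-in CTD residue groupings
#'
#' The standard seven-property, three-group partition of the 20 residues
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary-structure propensity and solvent
#' accessibility). Each partition covers the alphabet exactly.
#'
#' @return named list of integer vectors mapping each residue to group
#'   1, 2 or 3.
#' @export
ctd_groups <- function() {
  path <- system.file("extdata", "ctd_groups.tsv", package = "epiclass")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    g <- integer(0)
    for (k in 1:3) {
      res <- strsplit(tab[[paste0("group", k)]][i], "", fixed = TRUE)[[1]]
      g[res] <- k
    }
    stopifnot(identical(sort(names(g)), AA20))
    g[AA20]
  })
  names(out) <- tab$property
  out
}

# Accept a peptide set or a character vector; return a named character
# vector of validated uppercase sequences (pad allowed: encoders operate on
# fixed-length products too).
as_seqs <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(x$seq, x$id)
  } else {
    x <- toupper(as.character(x))
    if (!length(x)) stop("no sequences to encode")
    if (is.null(names(x))) names(x) <- paste0("pep", seq_along(x))
    if (!all(valid_sequence(x, allow_pad = TRUE)))
      stop("sequence(s) with characters outside the amino-acid alphabet")
    x
  }
}
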