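#' Remove duplicate peptide sequences
#'
#' Keeps the first occurrence of each exact sequence string; order is
#' preserved. Redundancy removal is exact-string only (no similarity
#' clustering).
#'
#' @param peps peptide set.
#' @return deduplicated peptide set.
#' @export
deduplicate <- function(peps) {
  peps[!duplicated(peps$seq), , drop = FALSE]
}

#' Filter peptides by length
#'
#' Keeps peptides with `lo <= nchar(seq) <= hi` (both bounds inclusive).
#' The defaults keep the 4-50 residue range used for linear B-cell
#' epitopes.
#'
#' @param peps peptide set.
#' @param lo,hi inclusive length bounds.
#' @return filtered peptide set.
#' @export
filter_length <- function(peps, lo = 4L, hi = 50L) {
  stopifnot(lo <= hi)
  n <- nchar(peps$seq)
  peps[n >= lo & n <= hi, , drop = FALSE]
}

#' Normalise peptides to a fixed length
#'
#' Extension/truncation: peptides longer than `target` keep the central
#' `target`-residue window (ties broken toward the N-terminus); shorter
#' peptides are padded symmetrically with `X` (the extra pad goes to the
#' C-terminus when the deficit is odd). Idempotent on length-`target`
#' input.
#'
#' @param peps peptide set (or character vector of sequences).
#' @param target fixed length (default 20).
#' @return object of the same shape with every sequence of length `target`.
#' @export
fix_length <- function(peps, target = 20L) {
  seqs <- if (is.data.frame(peps)) peps$seq else as.character(peps)
  out <- vapply(seqs, function(s) {
    L <- nchar(s)
    if (L == target) return(s)
    if (L > target) {
      start <- (L - target) %/% 2L + 1L
      substr(s, start, start + target - 1L)
    } else {
      pad <- target - L
      left <- pad %/% 2L
      paste0(strrep(PAD, left), s, strrep(PAD, pad - left))
    }
  }, character(1), USE.NAMES = FALSE)
  if (is.data.frame(peps)) {
    peps$seq <- out
    peps
  } else out
}

#' Build a one-vs-rest labeled dataset
#'
#' Positives are the named epitope class; negatives are the union of the
#' remaining epitope classes and the non-epitope pool. Sequences appearing
#' in both sides (the same peptide labeled in two classes) are purged from
#' the negatives and reported via a message, so the two sides are disjoint
#' by sequence.
#'
#' @param pools named list of peptide sets; names must include `class_name`,
#'   typically `IgG`, `IgE`, `IgA` and `nonBCE`.
#' @param class_name the positive class.
#' @param design design tag stored on the result.
#' @return `labeled_dataset`: list with `class_name`, `design`, `positives`,
#'   `negatives`, `seed`, `balanced`.
#' @export
build_one_vs_rest <- function(pools, class_name, design = "RealVar") {
  stopifnot(class_name %in% names(pools))
  pos <- pools[[class_name]]
  if (!nrow(pos)) stop("positive class '", class_name, "' is empty")
  neg <- do.call(rbind, pools[setdiff(names(pools), class_name)])
  rownames(neg) <- NULL
  clash <- neg$seq %in% pos$seq
  if (any(clash)) {
    message(sum(clash), " negative sequence(s) also labeled '", class_name,
            "' removed from negatives")
    neg <- neg[!clash, , drop = FALSE]
  }
  new_dataset(class_name, design, pos, neg)
}

new_dataset <- function(class_name, design, pos, neg,
                        seed = NA_integer_, balanced = FALSE) {
  structure(list(class_name = class_name, design = design,
                 positives = pos, negatives = neg,
                 seed = seed, balanced = balanced),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> class:", x$class_name, " design:", x$design,
      "\n  positives:", nrow(x$positives),
      " negatives:", nrow(x$negatives),
      if (x$balanced) " (balanced)" else "", "\n")
  invisible(x)
}

#' Balance a dataset by negative undersampling
#'
#' Negatives are sampled uniformly without replacement down to the number
#' of positives. If the negative pool is smaller than the positive set, the
#' positives are subsampled to the pool size instead and the result is
#' flagged (`attr(ds, "pool_limited")`). Reproducible under `seed`.
#'
#' @param ds `labeled_dataset`.
#' @param seed integer seed.
#' @return balanced `labeled_dataset`.
#' @export
balance <- function(ds, seed) {
  stopifnot(inherits(ds, "labeled_dataset"))
  np <- nrow(ds$positives); nn <- nrow(ds$negatives)
  out <- ds
  pool_limited <- FALSE
  if (nn > np) {
    out$negatives <- with_seed(seed, ds$negatives[sample.int(nn, np), ,
                                                  drop = FALSE])
  } else if (nn < np) {
    out$positives <- with_seed(seed, ds$positives[sample.int(np, nn), ,
                                                  drop = FALSE])
    pool_limited <- TRUE
  }
  out$design <- sub("^Real", "Balance", ds$design)
  out$seed <- as.integer(seed)
  out$balanced <- TRUE
  attr(out, "pool_limited") <- pool_limited
  out
}

#' Stratified independent split
#'
#' Randomly holds out `fraction` of the positives and `fraction` of the
#' negatives as an evaluation set; the remainder is the training set. The
#' two parts are disjoint and their union is the input.
#'
#' @param ds `labeled_dataset`.
#' @param fraction evaluation fraction in (0, 1); default 0.2.
#' @param seed integer seed.
#' @return list with `train` and `eval`, both `labeled_dataset`.
#' @export
split_independent <- function(ds, fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), fraction > 0, fraction < 1)
  np <- nrow(ds$positives); nn <- nrow(ds$negatives)
  kp <- round(np * fraction); kn <- round(nn * fraction)
  if (kp == 0L || kn == 0L || kp == np || kn == nn)
    stop("split would leave an empty side; adjust fraction or dataset size")
  idx <- with_seed(seed, list(p = sample.int(np, kp), n = sample.int(nn, kn)))
  mk <- function(pi, ni, tag) {
    d <- new_dataset(ds$class_name, paste0(ds$design, ".", tag),
                     ds$positives[pi, , drop = FALSE],
                     ds$negatives[ni, , drop = FALSE],
                     seed = as.integer(seed), balanced = ds$balanced)
    d
  }
  list(train = mk(setdiff(seq_len(np), idx$p), setdiff(seq_len(nn), idx$n),
                  "train"),
       eval = mk(idx$p, idx$n, "eval"))
}

#' Build a dataset under one of the four designs
#'
#' Composes the pipeline for the standard designs: `RealVar` (one-vs-rest
#' on variable-length pools), `BalanceVar` (negatives undersampled to the
#' positive count), `RealFix` (pools normalised to length 20 and
#' re-deduplicated before one-vs-rest) and `BalanceFix` (both).
#'
#' @param pools named list of deduplicated, length-filtered peptide sets.
#' @param class_name positive class.
#' @param design one of `"RealVar"`, `"BalanceVar"`, `"RealFix"`,
#'   `"BalanceFix"`.
#' @param seed seed for the balancing step.
#' @param target fixed length for the `*Fix` designs.
#' @return `labeled_dataset`.
#' @export
build_dataset <- function(pools, class_name,
                          design = c("RealVar", "BalanceVar",
                                     "RealFix", "BalanceFix"),
                          seed = 1L, target = 20L) {
  design <- match.arg(design)
  if (grepl("Fix$", design))
    pools <- lapply(pools, function(p) deduplicate(fix_length(p, target)))
  base <- if (grepl("Fix$", design)) "RealFix" else "RealVar"
  ds <- build_one_vs_rest(pools, class_name, design = base)
  if (startsWith(design, "Balance")) ds <- balance(ds, seed)
  ds
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# All sequences of a labeled dataset with a binary outcome vector.
dataset_xy <- function(ds) {
  list(seq = c(ds$positives$seq, ds$negatives$seq),
       y = rep(c(1L, 0L), c(nrow(ds$positives), nrow(ds$negatives))))
}
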