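#' Construct a peptide set
#'
#' A peptide set is a plain `data.frame` with columns `id`, `seq` and
#' `label`. Sequences are uppercased and validated against the 20-letter
#' amino-acid alphabet; the pad symbol `X` is only legal in fixed-length
#' products (set `allow_pad = TRUE`).
#'
#' @param seq character vector of sequences.
#' @param id character vector of identifiers (default `pep1..pepN`).
#' @param label class label recycled over peptides; one of
#'   `"IgG"`, `"IgE"`, `"IgA"`, `"nonBCE"`, `"unlabeled"`.
#' @param allow_pad allow the pad symbol `X` in sequences.
#' @param lenient if `TRUE`, drop records with out-of-alphabet characters
#'   (with a warning) instead of raising an error.
#' @return data.frame with columns `id`, `seq`, `label`.
#' @export
peptide_set <- function(seq, id = NULL, label = "unlabeled",
                        allow_pad = FALSE, lenient = FALSE) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) id <- paste0("pep", seq_along(seq))
  id <- as.character(id)
  stopifnot(length(id) == length(seq))
  label <- rep_len(as.character(label), length(seq))
  bad_label <- setdiff(unique(label), VALID_LABELS)
  if (length(bad_label))
    stop("invalid label(s): ", paste(bad_label, collapse = ", "))
  ok <- valid_sequence(seq, allow_pad = allow_pad)
  if (!all(ok)) {
    offenders <- paste0(id[!ok], " ('", seq[!ok], "')")
    if (lenient) {
      warning(sum(!ok), " record(s) with out-of-alphabet characters dropped: ",
              paste(utils::head(offenders, 5L), collapse = ", "))
      seq <- seq[ok]; id <- id[ok]; label <- label[ok]
    } else {
      stop("out-of-alphabet characters in record(s): ",
           paste(utils::head(offenders, 5L), collapse = ", "))
    }
  }
  data.frame(id = id, seq = seq, label = label, stringsAsFactors = FALSE)
}

# TRUE for every sequence over the standard alphabet (optionally + pad).
valid_sequence <- function(seq, allow_pad = FALSE) {
  alpha <- if (allow_pad) c(AA20, PAD) else AA20
  pat <- paste0("^[", paste(alpha, collapse = ""), "]+$")
  nzchar(seq) & grepl(pat, seq)
}

#' Read peptides from a FASTA file
#'
#' Sequences are uppercased; identifiers are taken verbatim from the header
#' up to the first whitespace. Records containing characters outside the
#' 20-letter amino-acid alphabet are rejected (default) or dropped with a
#' warning (`lenient = TRUE`).
#'
#' @param path FASTA file, wrapped or unwrapped lines.
#' @param label optional class label applied to all records.
#' @param lenient drop invalid records instead of erroring.
#' @return peptide set (see [peptide_set()]).
#' @export
read_fasta <- function(path, label = "unlabeled", lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) stop("empty FASTA file: ", path)
  first <- content[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA header at line ", first,
         ": expected '>' but found '", substr(trimws(lines[first]), 1, 20), "'")
  recs <- Biostrings::readAAStringSet(path)
  if (!length(recs)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  peptide_set(as.character(recs), id = ids, label = label, lenient = lenient)
}

#' Read peptides from a plain one-sequence-per-line file
#'
#' Blank lines are ignored; peptides are auto-named `pep1..pepN` in file
#' order (numbering stays contiguous across blank lines).
#'
#' @inheritParams read_fasta
#' @return peptide set.
#' @export
read_plain <- function(path, label = "unlabeled", lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  peptide_set(lines, label = label, lenient = lenient)
}

#' Write a peptide set as FASTA
#'
#' @param peps peptide set.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(peps, path, width = 60L) {
  x <- Biostrings::AAStringSet(peps$seq)
  names(x) <- peps$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a labeled epitope table
#'
#' Tab-separated table with columns `id`, `sequence` and `class`, the shape
#' of an exported epitope-database query.
#'
#' @param path TSV file.
#' @param lenient drop invalid records instead of erroring.
#' @return peptide set.
#' @export
read_epitope_table <- function(path, lenient = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "class")
  if (!all(need %in% names(tab)))
    stop("epitope table must have columns: ", paste(need, collapse = ", "))
  peptide_set(tab$sequence, id = tab$id, label = tab$class, lenient = lenient)
}

#' Write a peptide set as a labeled TSV manifest
#'
#' @param peps peptide set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epitope_table <- function(peps, path) {
  out <- data.frame(id = peps$id, sequence = peps$seq, class = peps$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
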