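#' @name preprocess
#' @title Post-alignment curation of aligned 16S reads
#' @description
#' After reads are aligned against a 16S reference model the alignment
#' carries long gap-only flanks and some reads align only patchily. The
#' curation implemented here is: find each read's aligned span, trim the
#' alignment to a fixed column window (defaults 710--2800, 1-based
#' inclusive), and discard reads whose longest run of contiguously aligned
#' (non-gap) bases falls below a threshold (default 437). Gap characters are
#' \code{-} and \code{.}.
NULL

gap_chars <- c("-", ".")
gap_regex <- "[^-.]"

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over \pkg{Biostrings} returning a named character vector of
#' equal-length aligned sequences.
#'
#' @param path file path.
#' @return \code{read_aligned_fasta}: named character vector.
#' @export
read_aligned_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  validate_alignment(seqs)
  seqs
}

#' @rdname read_aligned_fasta
#' @param seqs named character vector of aligned sequences.
#' @export
write_aligned_fasta <- function(seqs, path) {
  validate_alignment(seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

validate_alignment <- function(seqs) {
  if (length(seqs) == 0) stop("empty alignment")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("aligned sequences must have unique ids")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must all have the same length")
  invisible(seqs)
}

#' First and last aligned positions of each sequence
#'
#' @param seqs character vector of aligned sequences (a single string is
#'   fine).
#' @return data.frame with columns \code{first} and \code{last}: 1-based
#'   positions of the first/last non-gap character, \code{(0, 0)} for an
#'   all-gap sequence.
#' @examples
#' alignment_span("--AC-G--")   # first 3, last 6
#' @export
alignment_span <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences")
  first <- regexpr(gap_regex, seqs)
  rev_str <- vapply(strsplit(seqs, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1))
  from_end <- regexpr(gap_regex, rev_str)
  last <- ifelse(from_end < 0, 0L, nchar(seqs) - as.integer(from_end) + 1L)
  data.frame(first = ifelse(first < 0, 0L, as.integer(first)),
             last = as.integer(last),
             row.names = names(seqs))
}

#' Trim an alignment to a column window
#'
#' Retains alignment columns \code{start..end}, 1-based inclusive.
#'
#' @param seqs named character vector of aligned sequences.
#' @param start,end window bounds; defaults 710 and 2800.
#' @return the trimmed alignment (length \code{end - start + 1}).
#' @export
trim_alignment <- function(seqs, start = 710, end = 2800) {
  validate_alignment(seqs)
  len <- nchar(seqs[[1]])
  if (start < 1 || start > end) stop("need 1 <= start <= end")
  if (end > len) stop("end (", end, ") exceeds alignment length (", len, ")")
  out <- substr(seqs, start, end)
  names(out) <- names(seqs)
  out
}

#' Filter sequences by longest contiguously aligned run
#'
#' A sequence is kept iff its longest run of consecutive non-gap characters
#' is at least \code{min_len}; a run of exactly \code{min_len} is kept, one
#' base shorter is discarded. The report also records the total number of
#' aligned bases per sequence so the alternative "total bases" reading of the
#' threshold can be audited.
#'
#' @param seqs named character vector of aligned sequences.
#' @param min_len minimum run length (>= 1), default 437.
#' @return list with \code{kept} (the surviving alignment) and \code{report}
#'   (data.frame: id, longest_run, total_bases, kept).
#' @export
filter_by_contiguous_length <- function(seqs, min_len = 437) {
  validate_alignment(seqs)
  if (min_len < 1) stop("min_len must be >= 1")
  chars <- strsplit(seqs, "", fixed = TRUE)
  longest <- vapply(chars, function(ch) {
    r <- rle(!ch %in% gap_chars)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  }, integer(1))
  total <- vapply(chars, function(ch) sum(!ch %in% gap_chars), integer(1))
  keep <- longest >= min_len
  list(kept = seqs[keep],
       report = data.frame(id = names(seqs), longest_run = longest,
                           total_bases = total, kept = keep,
                           row.names = NULL, stringsAsFactors = FALSE))
}
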