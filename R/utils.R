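# Small shared helpers.  Sequences are plain upper-case character scalars
# over A/C/G/T (consensus sequences may additionally contain N); all
# coordinates are 0-based half-open unless a file format dictates
# otherwise.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param seq character scalar over A/C/G/T/N.
#' @return character scalar.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# Random DNA string of length n using the current RNG stream.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Split a sequence into characters once; used by pileup/consensus code.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# Total length of the union of 0-based half-open intervals.
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  stopifnot(length(start) == length(end), all(end > start))
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# Deterministic ordering used wherever ranking ties must break
# reproducibly: primary key descending, then lexicographic id.
order_score_desc_id <- function(score, id) order(-score, id, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
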