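# Read-to-target alignment records.  Alignment is an input contract:
# any mapper producing (read_id, target_id, mapq, aligned interval)
# records can feed the profilers.  Two built-in producers cover the
# synthetic workflow: `truth_alignments()` derives alignments from the
# simulator's known read coordinates (exact, handles substitutions),
# and `match_reads_exact()` is a naive exact-substring matcher over
# both strands for error-free fixtures.

# vectorized reverse complement
revcomp_v <- function(x) vapply(x, revcomp, character(1), USE.NAMES = FALSE)

#' Marker target locations across genomes
#'
#' A marker derived from gene family `f` of species `s` is present in
#' every genome of `s` carrying a gene of family `f` (family sequences
#' are identical across member genomes in the synthetic universe), so
#' reads overlapping any such gene instance align to the marker.
#'
#' @param db a `marker_db`.
#' @param genomes list of [genome_record()] objects.
#' @return target data.frame: `target_id` (marker id), `genome_id`,
#'   `contig`, `start`, `end`, `strand`.
#' @export
marker_targets <- function(db, genomes) {
  key <- paste(db$markers$species_taxid, db$markers$family90)
  mk_id <- setNames(db$markers$marker_id, key)
  do.call(rbind, lapply(genomes, function(g) {
    genes <- g$genes
    k <- paste(g$species_taxid, genes$family90)
    hit <- k %in% names(mk_id)
    if (!any(hit)) return(NULL)
    data.frame(target_id = unname(mk_id[k[hit]]), genome_id = g$genome_id,
               contig = genes$contig[hit], start = genes$start[hit],
               end = genes$end[hit], strand = genes$strand[hit],
               stringsAsFactors = FALSE)
  }))
}

#' Gene target locations across genomes
#'
#' @param genomes list of [genome_record()] objects.
#' @param target_id_col gene table column used as target id (default
#'   `"gene_id"`; use `"family90"` to pool family instances).
#' @return target data.frame as in [marker_targets()].
#' @export
gene_targets <- function(genomes, target_id_col = "gene_id") {
  do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    data.frame(target_id = g$genes[[target_id_col]],
               genome_id = g$genome_id, contig = g$genes$contig,
               start = g$genes$start, end = g$genes$end,
               strand = g$genes$strand, stringsAsFactors = FALSE)
  }))
}

#' Alignments from known read coordinates
#'
#' Intersects simulated reads (which carry their true source genome,
#' contig and interval) with target features on the same genome and
#' emits one alignment record per read/target overlap, expressed on the
#' target's forward (gene) frame.  Substitution errors present in the
#' read sequence are carried through, so downstream pileups see the true
#' sequenced bases.
#'
#' @param reads read data.frame from [simulate_reads()] (or the same
#'   schema for strain samples).
#' @param targets target data.frame ([marker_targets()],
#'   [gene_targets()]).
#' @param mapq MAPQ assigned to every record (default 42).
#' @param min_overlap minimum overlap in nt to report (default 1).
#' @return alignment data.frame: `read_id`, `marker_id`, `mapq`,
#'   `read_length`, `aligned_start`, `aligned_end` (0-based half-open on
#'   the target), `seq_on_target`, `qual_on_target`.
#' @export
truth_alignments <- function(reads, targets, mapq = 42L, min_overlap = 1L) {
  empty <- data.frame(read_id = character(0), marker_id = character(0),
                      mapq = integer(0), read_length = integer(0),
                      aligned_start = integer(0), aligned_end = integer(0),
                      seq_on_target = character(0),
                      qual_on_target = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(reads) || is.null(targets) || !nrow(targets)) return(empty)

  rk <- paste(reads$genome_id, reads$contig)
  tk <- paste(targets$genome_id, targets$contig)
  space <- intersect(unique(rk), unique(tk))
  out <- vector("list", length(space))
  for (si in seq_along(space)) {
    r <- reads[rk == space[si], , drop = FALSE]
    t <- targets[tk == space[si], , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(r$start + 1L, r$end),
      IRanges::IRanges(t$start + 1L, t$end),
      minoverlap = min_overlap)
    if (!length(ov)) next
    ri <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
    ov_start <- pmax(r$start[ri], t$start[ti])
    ov_end <- pmin(r$end[ri], t$end[ti])

    a_start <- ifelse(t$strand[ti] == "+", ov_start - t$start[ti],
                      t$end[ti] - ov_end)
    a_end <- ifelse(t$strand[ti] == "+", ov_end - t$start[ti],
                    t$end[ti] - ov_start)

    fwd_seq <- ifelse(r$strand[ri] == "-", revcomp_v(r$seq[ri]), r$seq[ri])
    fwd_qual <- ifelse(r$strand[ri] == "-",
                       vapply(r$qual[ri], function(q)
                         paste(rev(seq_chars(q)), collapse = ""),
                         character(1), USE.NAMES = FALSE),
                       r$qual[ri])
    seg <- substr(fwd_seq, ov_start - r$start[ri] + 1L,
                  ov_end - r$start[ri])
    segq <- substr(fwd_qual, ov_start - r$start[ri] + 1L,
                   ov_end - r$start[ri])
    flip <- t$strand[ti] == "-"
    if (any(flip)) {
      seg[flip] <- revcomp_v(seg[flip])
      segq[flip] <- vapply(segq[flip], function(q)
        paste(rev(seq_chars(q)), collapse = ""), character(1),
        USE.NAMES = FALSE)
    }
    out[[si]] <- data.frame(
      read_id = r$read_id[ri], marker_id = t$target_id[ti],
      mapq = mapq, read_length = nchar(r$seq[ri]),
      aligned_start = as.integer(a_start), aligned_end = as.integer(a_end),
      seq_on_target = seg, qual_on_target = segq,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Naive exact read matcher
#'
#' Finds every exact full-length occurrence of each read (or of its
#' reverse complement) inside each subject sequence.  Intended for
#' error-free synthetic fixtures; real samples should come with mapper
#' output instead.
#'
#' @param read_seqs named character vector of equal-length reads
#'   (`read_id -> sequence`).
#' @param subjects named character vector (`target_id -> sequence`).
#' @param mapq reported MAPQ (default 42).
#' @return alignment data.frame with the [truth_alignments()] schema
#'   (minus quality strings).
#' @export
match_reads_exact <- function(read_seqs, subjects, mapq = 42L) {
  stopifnot(!is.null(names(read_seqs)), !is.null(names(subjects)))
  widths <- nchar(read_seqs)
  if (length(unique(widths)) > 1L)
    stop("exact matcher requires equal-length reads")
  rl <- widths[1L]
  fwd <- Biostrings::DNAStringSet(read_seqs)
  pd <- list(`+` = Biostrings::PDict(fwd),
             `-` = Biostrings::PDict(Biostrings::reverseComplement(fwd)))
  res <- list()
  for (j in names(subjects)) {
    subj <- Biostrings::DNAString(subjects[[j]])
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPDict(pd[[strand]], subj)
      starts <- BiocGenerics::start(m)
      nhit <- S4Vectors::elementNROWS(starts)
      hit <- which(nhit > 0L)
      if (!length(hit)) next
      st <- unlist(starts[hit], use.names = FALSE) - 1L
      res[[length(res) + 1L]] <- data.frame(
        read_id = rep(names(read_seqs)[hit], unname(nhit[hit])),
        marker_id = j, mapq = mapq, read_length = rl,
        aligned_start = unname(st), aligned_end = unname(st) + rl,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(read_id = character(0), marker_id = character(0),
                      mapq = integer(0), read_length = integer(0),
                      aligned_start = integer(0), aligned_end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$read_id, out$marker_id, out$aligned_start,
            method = "radix"), , drop = FALSE]
}

#' Per-gene depth of coverage from alignments
#'
#' @param alignments alignment data.frame against gene targets.
#' @param gene_lengths named numeric vector `gene_id -> length` (nt).
#' @return named numeric depth vector over all genes (zeros included).
#' @export
gene_depths <- function(alignments, gene_lengths) {
  marker_coverage(alignments, gene_lengths, mode = "depth")
}
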