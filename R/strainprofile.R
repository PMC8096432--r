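# Strain-level profiling: per-sample consensus reconstruction of marker
# genotypes, sample/marker filtering, concatenated alignments, Kimura
# two-parameter distances, neighbor-joining trees and transmission
# inference.

#' Build a pileup for one marker
#'
#' Tallies, per marker position, the base counts and base-quality sums
#' of all alignment records of one sample against that marker.
#'
#' @param alignments alignment rows for a single marker, carrying
#'   `aligned_start`, `seq_on_target`, `qual_on_target` (see
#'   [truth_alignments()]).
#' @param marker_length marker length (nt).
#' @param marker_id id recorded on the pileup.
#' @return object of class `pileup`: `counts` (4 x L integer matrix,
#'   rows A/C/G/T), `qual_sum` (length-L numeric), `n_reads`.
#' @export
build_pileup <- function(alignments, marker_length, marker_id = NULL) {
  L <- as.integer(marker_length)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  qual_sum <- numeric(L)
  n_reads <- length(unique(alignments$read_id))
  if (nrow(alignments)) {
    if (any(alignments$aligned_end > L))
      stop("alignment beyond marker length")
    lens <- nchar(alignments$seq_on_target)
    pos <- sequence(lens) + rep(alignments$aligned_start, lens)  # 1-based
    bases <- unlist(strsplit(alignments$seq_on_target, "", fixed = TRUE),
                    use.names = FALSE)
    quals <- unlist(lapply(alignments$qual_on_target, function(q)
      utf8ToInt(q) - 33L), use.names = FALSE)
    bi <- match(bases, DNA_BASES)
    ok <- !is.na(bi)
    counts[] <- tabulate(bi[ok] + 4L * (pos[ok] - 1L), nbins = 4L * L)
    qs <- rowsum(quals[ok], pos[ok])
    qual_sum[as.integer(rownames(qs))] <- qs[, 1L]
  }
  structure(list(marker_id = marker_id %||% alignments$marker_id[1L],
                 marker_length = L, counts = counts,
                 qual_sum = qual_sum, n_reads = n_reads),
            class = "pileup")
}

#' Call a consensus marker sequence from a pileup
#'
#' Each position is called as the majority base when the column's mean
#' base quality is at least `min_qual` and the major allele's frequency
#' is at least `min_dominance`; otherwise (including uncovered
#' positions) it is ambiguous (`N`).  Breadth of coverage counts only
#' unambiguously called positions.  Markers reconstructed from fewer
#' than `min_reads` reads or with breadth below `min_breadth` are
#' rejected; rejections are returned as values (`status` field), not
#' errors.
#'
#' @param pileup a [build_pileup()] result.
#' @param sample_id recorded on the result.
#' @param min_reads minimum supporting reads (default 8).
#' @param min_breadth minimum breadth of coverage (default 0.8).
#' @param min_qual minimum mean column quality (default 30).
#' @param min_dominance minimum major-allele frequency (default 0.8).
#' @return object of class `consensus_marker`: `marker_id`, `sample_id`,
#'   `seq` (over A/C/G/T/N), `breadth`, `n_reads`, `status` (`"ok"` or a
#'   rejection reason).
#' @export
call_consensus <- function(pileup, sample_id = NA_character_,
                           min_reads = 8L, min_breadth = 0.8,
                           min_qual = 30, min_dominance = 0.8) {
  stopifnot(inherits(pileup, "pileup"))
  cm <- pileup$counts
  cov <- colSums(cm)
  major_i <- max.col(t(cm), ties.method = "first")
  major_n <- cm[cbind(major_i, seq_len(ncol(cm)))]
  mean_q <- ifelse(cov > 0, pileup$qual_sum / cov, 0)
  called <- cov > 0 & mean_q >= min_qual & major_n / pmax(cov, 1L) >= min_dominance
  bases <- rep("N", pileup$marker_length)
  bases[called] <- DNA_BASES[major_i[called]]
  breadth <- sum(called) / pileup$marker_length

  status <- if (pileup$n_reads < min_reads) {
    sprintf("rejected: %d read(s) < %d", pileup$n_reads, min_reads)
  } else if (breadth < min_breadth) {
    sprintf("rejected: breadth %.3f < %.2f", breadth, min_breadth)
  } else "ok"
  structure(list(marker_id = pileup$marker_id, sample_id = sample_id,
                 seq = paste(bases, collapse = ""), breadth = breadth,
                 n_reads = pileup$n_reads, status = status),
            class = "consensus_marker")
}

#' Consensus markers of one sample
#'
#' Groups a sample's alignments by marker, builds pileups and calls
#' consensus sequences, returning only the accepted markers.
#'
#' @param alignments alignment data.frame with pileup columns.
#' @param marker_lengths named vector `marker_id -> length`.
#' @param sample_id sample label.
#' @param ... thresholds for [call_consensus()].
#' @return named list `marker_id -> consensus_marker` of accepted
#'   markers; rejected markers are reported in the `"rejected"`
#'   attribute (named character vector of reasons).
#' @export
sample_consensus <- function(alignments, marker_lengths, sample_id, ...) {
  by_marker <- split(alignments, alignments$marker_id)
  accepted <- list()
  rejected <- character(0)
  for (m in names(by_marker)) {
    if (!m %in% names(marker_lengths)) stop("unknown marker ", m)
    cons <- call_consensus(
      build_pileup(by_marker[[m]], marker_lengths[[m]], m),
      sample_id = sample_id, ...)
    if (cons$status == "ok") accepted[[m]] <- cons
    else rejected[[m]] <- cons$status
  }
  structure(accepted, rejected = rejected)
}

#' Joint sample/marker filtering
#'
#' Alternates two rules until a fixed point: drop samples retaining
#' fewer than `sample_with_n_markers` markers, then drop markers present
#' in fewer than `marker_in_n_samples` (fraction) of the remaining
#' samples.  The result satisfies both thresholds simultaneously.
#'
#' @param presence data.frame with columns `sample_id`, `marker_id`
#'   (one row per accepted sample/marker combination).
#' @param sample_with_n_markers minimum markers per sample (default 20).
#' @param marker_in_n_samples minimum fraction of samples per marker
#'   (default 0.8).
#' @return list: `samples`, `markers` (retained ids), `presence`
#'   (filtered data.frame).
#' @export
filter_samples_and_markers <- function(presence, sample_with_n_markers = 20L,
                                       marker_in_n_samples = 0.8) {
  stopifnot(all(c("sample_id", "marker_id") %in% names(presence)))
  pres <- unique(presence[c("sample_id", "marker_id")])
  repeat {
    n0 <- nrow(pres)
    keep_s <- names(which(table(pres$sample_id) >= sample_with_n_markers))
    pres <- pres[pres$sample_id %in% keep_s, , drop = FALSE]
    if (!nrow(pres)) stop("insufficient data: all samples dropped")
    n_samples <- length(unique(pres$sample_id))
    keep_m <- names(which(
      table(pres$marker_id) >= marker_in_n_samples * n_samples))
    pres <- pres[pres$marker_id %in% keep_m, , drop = FALSE]
    if (!nrow(pres)) stop("insufficient data: all markers dropped")
    if (nrow(pres) == n0) break
  }
  list(samples = sort(unique(pres$sample_id)),
       markers = sort(unique(pres$marker_id)),
       presence = pres)
}

#' Trim consensus boundaries
#'
#' Removes the leading and trailing `trim` bases, which are typically
#' supported by lower coverage due to mapping boundary effects.
#'
#' @param seq consensus sequence (character scalar).
#' @param trim bases removed from each end (default 50).
#' @return trimmed sequence, or `NULL` (with a warning) when the
#'   sequence is not longer than `2 * trim`.
#' @export
trim_consensus <- function(seq, trim = 50L) {
  n <- nchar(seq)
  if (n <= 2L * trim) {
    warning("marker of ", n, " nt dropped by trimming (<= ", 2L * trim,
            " nt)")
    return(NULL)
  }
  substr(seq, trim + 1L, n - trim)
}

#' Concatenated marker alignment across samples
#'
#' Builds the per-sample concatenation of trimmed consensus sequences
#' over a fixed lexicographic marker order.  Because consensus sequences
#' are reconstructed against a common reference marker, sequences of one
#' marker have equal length across samples and columnwise concatenation
#' is itself a valid multiple alignment; a marker missing from a sample
#' is gap-filled with `N`.  An external aligner hook can replace this
#' when indel-containing inputs are expected.
#'
#' @param consensus_sets named list `sample_id -> (named list
#'   marker_id -> sequence)`.
#' @param markers marker ids to include (default: union over samples).
#' @param trim boundary trim per marker (default 50; see
#'   [trim_consensus()]).
#' @return named character vector of aligned sequences with attribute
#'   `"marker_order"`; all elements have equal length.
#' @export
concatenate_alignment <- function(consensus_sets, markers = NULL,
                                  trim = 50L) {
  markers <- sort(markers %||%
                    unique(unlist(lapply(consensus_sets, names))))
  # establish per-marker length and check consistency
  mlen <- setNames(rep(NA_integer_, length(markers)), markers)
  for (s in names(consensus_sets)) {
    for (m in intersect(names(consensus_sets[[s]]), markers)) {
      n <- nchar(consensus_sets[[s]][[m]])
      if (is.na(mlen[[m]])) mlen[[m]] <- n
      else if (mlen[[m]] != n)
        stop("length mismatch for marker ", m,
             ": indel-containing input needs an external aligner")
    }
  }
  keep <- markers[!is.na(mlen) & mlen > 2L * trim]
  if (!length(keep)) stop("no markers survive trimming")
  tlen <- mlen[keep] - 2L * trim

  out <- vapply(names(consensus_sets), function(s) {
    paste(vapply(keep, function(m) {
      sq <- consensus_sets[[s]][[m]]
      if (is.null(sq)) strrep("N", tlen[[m]])
      else substr(sq, trim + 1L, nchar(sq) - trim)
    }, character(1)), collapse = "")
  }, character(1))
  attr(out, "marker_order") <- keep
  out
}

#' Kimura two-parameter distance
#'
#' Evolutionary distance between two aligned sequences correcting for
#' unequal transition/transversion rates:
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` and `Q` the
#' transition and transversion fractions over comparable sites (sites
#' where either sequence is `N` are excluded).
#'
#' @param seq_a,seq_b equal-length sequences over A/C/G/T/N.
#' @return non-negative distance; `NA` when no comparable sites exist.
#' @export
kimura2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  a <- seq_chars(seq_a); b <- seq_chars(seq_b)
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  transitions <- diff & (purine_a == purine_b)
  P <- sum(transitions) / n
  Q <- sum(diff & !transitions) / n
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (arg <= 0) stop("Kimura distance saturated (argument <= 0)")
  max(0, -0.5 * log(arg))
}

#' Pairwise Kimura distance matrix
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
strain_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(d)
  chars <- lapply(seqs, seq_chars)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a %in% DNA_BASES & b %in% DNA_BASES
    nn <- sum(ok)
    if (nn == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
    aa <- a[ok]; bb <- b[ok]
    diff <- aa != bb
    transitions <- diff & ((aa %in% c("A", "G")) == (bb %in% c("A", "G")))
    P <- sum(transitions) / nn
    Q <- sum(diff & !transitions) / nn
    arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
    if (arg <= 0) stop("Kimura distance saturated (argument <= 0)")
    d[i, j] <- d[j, i] <- max(0, -0.5 * log(arg))
  }
  d
}

#' Neighbor-joining strain tree
#'
#' Builds an unrooted neighbor-joining tree from a strain distance
#' matrix.  This is the built-in tree builder; a maximum-likelihood tool
#' can be plugged in externally when higher accuracy is needed.
#'
#' @param d symmetric distance matrix (>= 3 samples, finite entries).
#' @return an [ape::phylo] tree with the samples as tips.
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 samples")
  if (any(is.na(d)) || any(!is.finite(d))) stop("missing distances")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Tree-normalized pairwise distances
#'
#' Leaf-to-leaf path lengths divided by the total branch length of the
#' tree, yielding distances in `[0, 1]`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return list of class `strain_dist`: `distances` (matrix),
#'   `total_branch_length`, `normalization = "tree"`.
#' @export
normalized_tree_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  total <- sum(tree$edge.length)
  d <- ape::cophenetic.phylo(tree)
  d <- if (total > 0) d / total else d * 0
  d <- d[order(rownames(d)), order(colnames(d)), drop = FALSE]
  structure(list(distances = d, total_branch_length = total,
                 normalization = "tree"), class = "strain_dist")
}

#' Infer strain transmission events
#'
#' A threshold defining "identical strains" is set at the first
#' percentile (linear interpolation between order statistics) of the
#' distance distribution over *unrelated* sample pairs, bounding the
#' theoretical false-discovery rate at 1%.  Because a linearly
#' interpolated percentile can leave marginally more than the target
#' fraction of unrelated distances strictly below it, the threshold is
#' additionally capped at the `floor(n * p) + 1`-th unrelated order
#' statistic, which guarantees the bound by construction.  For
#' longitudinal subjects only the earliest sample per subject is kept
#' (ties broken by sample id); samples absent from the metadata count
#' as unrelated.  Related pairs with a distance strictly below the
#' threshold are reported as potential transmission events.
#'
#' @param dist a `strain_dist` (or a plain normalized distance matrix).
#' @param metadata data.frame `sample_id`, `subject_id`,
#'   `collection_date` (sortable strings or dates).
#' @param related_pairs data.frame `sample_a`, `sample_b` of sample
#'   pairs with a relation of interest.
#' @param percentile threshold percentile of the unrelated distribution
#'   (default 0.01).
#' @return list of class `transmission_calls`: `threshold`, `events`
#'   (data.frame `sample_a`, `sample_b`, `distance`), `n_unrelated_pairs`,
#'   `unrelated_below_threshold` (fraction).
#' @export
infer_transmission <- function(dist, metadata, related_pairs,
                               percentile = 0.01) {
  d <- if (inherits(dist, "strain_dist")) dist$distances else dist
  samples <- rownames(d)

  meta <- metadata[metadata$sample_id %in% samples, , drop = FALSE]
  meta <- meta[order(meta$subject_id, meta$collection_date,
                     meta$sample_id), , drop = FALSE]
  keep <- meta$sample_id[!duplicated(meta$subject_id)]
  keep <- sort(unique(c(keep, setdiff(samples, metadata$sample_id))))
  d <- d[keep, keep, drop = FALSE]

  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rel <- unique(pair_key(related_pairs$sample_a, related_pairs$sample_b))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(sample_a = rownames(d)[idx[, 1L]],
                      sample_b = colnames(d)[idx[, 2L]],
                      distance = d[idx], stringsAsFactors = FALSE)
  pairs$related <- pair_key(pairs$sample_a, pairs$sample_b) %in% rel

  unrelated <- pairs$distance[!pairs$related]
  if (length(unrelated) < 100L)
    warning("only ", length(unrelated),
            " unrelated pairs; percentile threshold may be unstable")
  threshold <- as.numeric(quantile(unrelated, percentile, type = 7,
                                   names = FALSE))
  cap_rank <- floor(length(unrelated) * percentile) + 1L
  if (cap_rank <= length(unrelated))
    threshold <- min(threshold, sort(unrelated)[cap_rank])
  events <- pairs[pairs$related & pairs$distance < threshold,
                  c("sample_a", "sample_b", "distance"), drop = FALSE]
  rownames(events) <- NULL
  structure(list(threshold = threshold, events = events,
                 n_unrelated_pairs = length(unrelated),
                 unrelated_below_threshold =
                   mean(unrelated < threshold)),
            class = "transmission_calls")
}

#' @export
print.transmission_calls <- function(x, ...) {
  cat(sprintf(
    "<transmission_calls  threshold %.4g, %d event(s), %d unrelated pair(s)>\n",
    x$threshold, nrow(x$events), x$n_unrelated_pairs))
  invisible(x)
}

#' Per-sample polymorphic-site rates
#'
#' Fraction of covered marker positions that could not be called
#' unambiguously, per sample — a quick data-quality readout.
#'
#' @param consensus_sets named list `sample_id -> (named list
#'   marker_id -> consensus sequence)`.
#' @return data.frame `sample_id`, `n_sites`, `n_ambiguous`, `rate`.
#' @export
polymorphic_rates <- function(consensus_sets) {
  do.call(rbind, lapply(names(consensus_sets), function(s) {
    seqs <- unlist(consensus_sets[[s]], use.names = FALSE)
    ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    data.frame(sample_id = s, n_sites = length(ch),
               n_ambiguous = sum(ch == "N"),
               rate = if (length(ch)) mean(ch == "N") else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
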