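# Taxonomic profiling from read-to-marker alignments: per-marker depth,
# quantile-trimmed robust clade coverage, rank-complete relative
# abundances and estimation of the unknown community fraction.
#
# Alignment records are rows of a data.frame with columns read_id,
# marker_id, mapq, read_length, aligned_start, aligned_end (0-based
# half-open on the marker).

#' Quality-filter alignments
#'
#' Retains exactly the alignments with `read_length >= min_read_len` and
#' `mapq >= min_mapq` (defaults 70 bp and 5).
#'
#' @param alignments alignment data.frame.
#' @param min_read_len,min_mapq inclusive retention thresholds.
#' @return the filtered data.frame.
#' @export
filter_alignments <- function(alignments, min_read_len = 70L, min_mapq = 5L) {
  keep <- alignments$read_length >= min_read_len &
    alignments$mapq >= min_mapq
  alignments[keep, , drop = FALSE]
}

# Multi-mapping resolution: each read contributes to exactly one marker
# (highest MAPQ, then most aligned bases, then lexicographic marker_id).
dedupe_alignments <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  o <- order(alignments$read_id, -alignments$mapq,
             -(alignments$aligned_end - alignments$aligned_start),
             alignments$marker_id, method = "radix")
  a <- alignments[o, , drop = FALSE]
  a[!duplicated(a$read_id), , drop = FALSE]
}

#' Per-marker depth of coverage
#'
#' Depth of a marker is the total number of bases aligned to it divided
#' by its length (reads-per-base depth).  With `mode = "reads"` the
#' number of aligned reads is used instead of aligned bases.
#'
#' @param alignments filtered alignment data.frame.
#' @param marker_lengths named numeric vector, `marker_id -> length` (nt);
#'   every marker in `alignments` must be present.
#' @param mode `"depth"` (default) or `"reads"`.
#' @return named numeric vector of depths over all markers in
#'   `marker_lengths` (zero where unaligned).
#' @export
marker_coverage <- function(alignments, marker_lengths, mode = c("depth", "reads")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(marker_lengths)))
  unknown <- setdiff(unique(alignments$marker_id), names(marker_lengths))
  if (length(unknown))
    stop("alignments reference markers absent from the database: ",
         paste(head(unknown, 3L), collapse = ", "))
  depth <- setNames(numeric(length(marker_lengths)), names(marker_lengths))
  if (nrow(alignments)) {
    contrib <- if (mode == "depth") {
      alignments$aligned_end - alignments$aligned_start
    } else rep(1, nrow(alignments))
    sums <- tapply(contrib, alignments$marker_id, sum)
    depth[names(sums)] <- as.numeric(sums)
    if (mode == "depth") depth <- depth / marker_lengths
  }
  depth
}

#' Robust (quantile-trimmed) clade coverage
#'
#' The clade's coverage is the robust average of its marker depths:
#' depths are sorted and `floor(stat_q * n)` entries are dropped from
#' each end before taking the arithmetic mean.  The depth vector is
#' expected to include zeros for the clade's unaligned markers, so that
#' clades supported by few markers are down-weighted.
#'
#' @param depths numeric vector of per-marker depths (with zeros).
#' @param stat_q trimming quantile per tail, in `[0, 0.5)` (default 0.2).
#' @return scalar coverage (0 when no markers remain).
#' @export
clade_coverage <- function(depths, stat_q = 0.2) {
  stopifnot(stat_q >= 0, stat_q < 0.5)
  n <- length(depths)
  if (n == 0L) return(0)
  k <- floor(stat_q * n)
  s <- sort(depths)
  mean(s[(k + 1L):(n - k)])
}

#' Aggregate species coverages over the taxonomy
#'
#' Coverage of an internal clade is the sum of the coverages of its
#' detected descendant species.
#'
#' @param species_coverages named numeric vector, `taxid -> coverage`
#'   (species only).
#' @param taxonomy taxonomy data.frame.
#' @return data.frame of all clades with nonzero coverage: `taxid`,
#'   `rank`, `coverage`.
#' @export
aggregate_taxonomy <- function(species_coverages, taxonomy) {
  validate_taxonomy(taxonomy)
  sp <- species_coverages[species_coverages > 0]
  if (!length(sp))
    return(data.frame(taxid = integer(0), rank = character(0),
                      coverage = numeric(0), stringsAsFactors = FALSE))
  taxids <- as.integer(names(sp))
  if (any(!taxids %in% taxonomy$taxid))
    stop("species taxid(s) missing from taxonomy: ",
         paste(setdiff(taxids, taxonomy$taxid), collapse = ", "))
  desc <- species_descendants(taxonomy)
  cov <- vapply(as.character(taxonomy$taxid), function(t)
    sum(sp[as.character(intersect(desc[[t]], taxids))]), numeric(1))
  out <- data.frame(taxid = taxonomy$taxid, rank = taxonomy$rank,
                    coverage = unname(cov), stringsAsFactors = FALSE)
  out[out$coverage > 0, , drop = FALSE]
}

#' Normalize clade coverages to relative abundances
#'
#' Within each rank, coverages are normalized to percentages summing to
#' 100 over the detected clades.
#'
#' @param clade_coverages output of [aggregate_taxonomy()].
#' @return same data.frame with a `relative_abundance` column (percent);
#'   zero rows when nothing was detected.
#' @export
relative_abundance <- function(clade_coverages) {
  stopifnot(all(clade_coverages$coverage >= 0))
  out <- clade_coverages
  out$relative_abundance <- NA_real_
  for (r in unique(out$rank)) {
    i <- out$rank == r
    tot <- sum(out$coverage[i])
    out$relative_abundance[i] <- if (tot > 0)
      100 * out$coverage[i] / tot else 0
  }
  out[out$coverage > 0, , drop = FALSE]
}

#' Estimate the unknown fraction of a community
#'
#' The number of reads explained by the detected species is estimated as
#' the sum over species of `coverage * avg_genome_length / read_length`;
#' the unknown fraction is the percentage of total reads left
#' unexplained (clamped at 0).
#'
#' @param total_reads total reads in the sample (mapped + unmapped).
#' @param species_coverages named numeric vector, `taxid -> coverage`.
#' @param avg_genome_lengths named numeric vector, `taxid -> genome
#'   length` (nt), covering all detected species.
#' @param read_length mean read length of the sample (nt, > 0).
#' @return unknown fraction in percent.
#' @export
estimate_unknown <- function(total_reads, species_coverages,
                             avg_genome_lengths, read_length) {
  if (read_length <= 0) stop("read length must be positive")
  sp <- species_coverages[species_coverages > 0]
  if (!length(sp)) return(100)
  lens <- avg_genome_lengths[names(sp)]
  if (any(is.na(lens) | lens <= 0))
    stop("missing or non-positive genome length for detected species")
  explained <- sum(sp * lens) / read_length
  100 * max(0, total_reads - explained) / total_reads
}

#' Taxonomic profile of one sample
#'
#' Full profiling pipeline: alignments are quality-filtered
#' ([filter_alignments()]) and multi-mapped reads resolved to their best
#' marker; per-marker depths are computed ([marker_coverage()]); species
#' detection proceeds in two passes, first detecting species with at
#' least one aligned *unique* marker, then excluding from every species'
#' depth vector the quasi-markers shared with an already-detected
#' species; a species is reported when more than `detect_frac` of its
#' (retained) markers have nonzero depth, with coverage given by the
#' trimmed robust average ([clade_coverage()]).  Coverages are summed up
#' the taxonomy, normalized per rank to percentages and, when
#' `total_reads` is given, rescaled so that known abundances plus the
#' estimated unknown fraction total 100.
#'
#' @param alignments alignment data.frame (see [filter_alignments()]).
#' @param db a `marker_db` object.
#' @param total_reads total reads in the sample; `NULL` disables unknown
#'   estimation.
#' @param stat_q trimming quantile (default 0.2).
#' @param min_read_len,min_mapq alignment quality thresholds (70, 5).
#' @param detect_frac minimum fraction of markers with nonzero depth for
#'   a species to be reported (default 1/3).
#' @param depth_mode `"depth"` or `"reads"`, see [marker_coverage()].
#' @return object of class `tax_profile`: data.frame (`taxid`, `rank`,
#'   `taxonomy_path`, `taxid_path`, `relative_abundance`) with attributes
#'   `unknown_fraction`, `total_reads` and `species_coverage`.
#' @export
profile_taxa <- function(alignments, db, total_reads = NULL, stat_q = 0.2,
                         min_read_len = 70L, min_mapq = 5L,
                         detect_frac = 1 / 3,
                         depth_mode = c("depth", "reads")) {
  stopifnot(inherits(db, "marker_db"))
  depth_mode <- match.arg(depth_mode)
  markers <- db$markers

  aln <- filter_alignments(alignments, min_read_len, min_mapq)
  aln <- dedupe_alignments(aln)
  mlen <- setNames(markers$length, markers$marker_id)
  depths <- marker_coverage(aln, mlen, mode = depth_mode)

  # pass 1: species supported by at least one unique marker
  hit <- depths > 0
  detected_unique <- unique(
    markers$species_taxid[markers$is_unique & hit[markers$marker_id]])

  # pass 2: per-species robust coverage over retained markers
  sp_cov <- numeric(0)
  for (taxid in unique(markers$species_taxid)) {
    m <- markers[markers$species_taxid == taxid, , drop = FALSE]
    shared_with_detected <- vapply(m$ext_species, function(e)
      length(intersect(e, setdiff(detected_unique, taxid))) > 0, logical(1))
    m <- m[m$is_unique | !shared_with_detected, , drop = FALSE]
    if (!nrow(m)) next
    d <- depths[m$marker_id]
    if (mean(d > 0) <= detect_frac) next
    cov <- clade_coverage(d, stat_q)
    if (cov > 0) sp_cov[as.character(taxid)] <- cov
  }

  clades <- aggregate_taxonomy(sp_cov, db$taxonomy)
  prof <- relative_abundance(clades)

  unknown <- 0
  if (!is.null(total_reads)) {
    rl <- if (nrow(aln)) mean(aln$read_length) else 1
    glen <- setNames(db$taxonomy$avg_genome_length,
                     as.character(db$taxonomy$taxid))
    unknown <- estimate_unknown(total_reads, sp_cov, glen, rl)
    prof$relative_abundance <- prof$relative_abundance * (100 - unknown) / 100
  }

  paths <- if (nrow(prof)) taxonomy_paths(db$taxonomy) else NULL
  out <- data.frame(
    taxid = prof$taxid, rank = prof$rank,
    taxonomy_path = if (nrow(prof))
      paths$taxonomy_path[match(prof$taxid, paths$taxid)] else character(0),
    taxid_path = if (nrow(prof))
      paths$taxid_path[match(prof$taxid, paths$taxid)] else character(0),
    relative_abundance = prof$relative_abundance,
    stringsAsFactors = FALSE)
  out <- out[order(match(out$rank, RANK_ORDER), out$taxonomy_path), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tax_profile", "data.frame"),
            unknown_fraction = unknown,
            total_reads = total_reads %||% NA_integer_,
            species_coverage = sp_cov)
}

#' @export
print.tax_profile <- function(x, ...) {
  cat(sprintf("<tax_profile  %d clade(s), unknown %.2f%%>\n",
              nrow(x), attr(x, "unknown_fraction")))
  print(as.data.frame(x), ...)
  invisible(x)
}
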