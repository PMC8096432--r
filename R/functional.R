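# Tiered functional profiling: nucleotide-level assignment of reads to
# pangenome gene families with a database-sequence coverage filter,
# translated-search fallback with identity and top-score filters,
# species stratification, regrouping to broader feature systems and CPM
# renormalization.
#
# A functional profile is a data.frame (family, stratum, abundance)
# with a `units` attribute ("RPK" or "CPM"); the stratum is a species
# taxid (as character) for nucleotide-tier weight or "unclassified" for
# translated-tier weight.

functional_profile_df <- function(family, stratum, abundance,
                                  units = "RPK") {
  structure(data.frame(family = family, stratum = stratum,
                       abundance = abundance, stringsAsFactors = FALSE),
            class = c("functional_profile", "data.frame"), units = units)
}

#' Community totals of a functional profile
#'
#' @param profile a functional profile data.frame.
#' @return named numeric vector `family -> total abundance` (sum over
#'   strata).
#' @export
community_totals <- function(profile) {
  tot <- tapply(profile$abundance, profile$family, sum)
  setNames(as.numeric(tot), names(tot))
}

#' Database-sequence coverage filter
#'
#' For each database sequence, the fraction of its positions covered by
#' the union of its hit intervals is computed; when it falls below
#' `min_covered_fraction` *all* hits to that sequence are discarded.
#' The filter is idempotent and independent of hit order.
#'
#' @param hits data.frame `read_id`, `target_id`, `start`, `end`
#'   (0-based half-open on the target), plus any other columns.
#' @param target_lengths named numeric vector `target_id -> length`.
#' @param min_covered_fraction inclusive retention threshold (default
#'   0.5).
#' @return the surviving hits.
#' @export
coverage_filter <- function(hits, target_lengths,
                            min_covered_fraction = 0.5) {
  if (!nrow(hits)) return(hits)
  unknown <- setdiff(unique(hits$target_id), names(target_lengths))
  if (length(unknown)) stop("hits to targets of unknown length: ",
                            paste(head(unknown, 3L), collapse = ", "))
  by_target <- split(seq_len(nrow(hits)), hits$target_id)
  keep_target <- vapply(names(by_target), function(t) {
    i <- by_target[[t]]
    interval_union_length(hits$start[i], hits$end[i]) /
      target_lengths[[t]] >= min_covered_fraction
  }, logical(1))
  hits[hits$target_id %in% names(by_target)[keep_target], , drop = FALSE]
}

#' Nucleotide-tier read assignment
#'
#' Each read is assigned to its best-scoring pangene (ties broken by
#' lexicographic target id).  With `multi_hit_k > 1` the read's weight
#' is instead split equally over its up-to-`k` best pangenes.  Reads
#' with no surviving hits are emitted as unmapped for the translated
#' tier.
#'
#' @param hits coverage-filtered hits with columns `read_id`,
#'   `target_id`, `score`.
#' @param read_ids all read ids of the sample (so that fully unaligned
#'   reads appear in the unmapped set); defaults to the reads present in
#'   `hits`.
#' @param multi_hit_k maximum targets per read (default 1).
#' @return list: `assignments` (data.frame `read_id`, `target_id`,
#'   `weight`), `unmapped` (character vector).
#' @export
nucleotide_assign <- function(hits, read_ids = NULL, multi_hit_k = 1L) {
  read_ids <- read_ids %||% unique(hits$read_id)
  if (!nrow(hits)) {
    return(list(assignments = data.frame(read_id = character(0),
                                         target_id = character(0),
                                         weight = numeric(0)),
                unmapped = read_ids))
  }
  o <- order(hits$read_id, -hits$score, hits$target_id, method = "radix")
  h <- hits[o, , drop = FALSE]
  rank_in_read <- sequence(rle(h$read_id)$lengths)
  h <- h[rank_in_read <= multi_hit_k, , drop = FALSE]
  n_per_read <- table(h$read_id)
  assignments <- data.frame(
    read_id = h$read_id, target_id = h$target_id,
    weight = 1 / as.numeric(n_per_read[h$read_id]),
    stringsAsFactors = FALSE)
  list(assignments = assignments,
       unmapped = setdiff(read_ids, h$read_id))
}

#' Translated-tier read assignment
#'
#' Per read: hits below `min_identity` percent identity are dropped,
#' then only hits scoring within `top_fraction` of the read's best
#' surviving hit are kept (score `>= (1 - top_fraction) * best`), and
#' the read's weight is split equally over the distinct protein families
#' of the survivors.  Reads with no surviving hits stay unclassified.
#'
#' @param hits data.frame `read_id`, `family_id`, `identity` (percent),
#'   `score`; pass the hits through [coverage_filter()] on the protein
#'   targets first.
#' @param min_identity inclusive identity floor (default 80).
#' @param top_fraction score window below the best hit (default 0.01).
#' @return data.frame `read_id`, `family_id`, `weight`.
#' @export
translated_assign <- function(hits, min_identity = 80, top_fraction = 0.01) {
  h <- hits[hits$identity >= min_identity, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(read_id = character(0), family_id = character(0),
                      weight = numeric(0)))
  best <- tapply(h$score, h$read_id, max)
  h <- h[h$score >= (1 - top_fraction) * best[h$read_id], , drop = FALSE]
  h <- unique(h[c("read_id", "family_id")])
  n <- table(h$read_id)
  data.frame(read_id = h$read_id, family_id = h$family_id,
             weight = 1 / as.numeric(n[h$read_id]),
             stringsAsFactors = FALSE)
}

#' Reads-per-kilobase family abundances
#'
#' Sums read weights per (family, stratum) and divides by the family
#' length in kilobases.  Nucleotide-tier strata carry the pangene's
#' species; translated-tier weight goes to the `"unclassified"`
#' stratum.
#'
#' @param assignments data.frame `family`, `stratum`, `weight`.
#' @param family_lengths named numeric vector `family -> length in nt`
#'   (use `3 * aa` for protein families).
#' @return functional profile (units RPK).
#' @export
family_abundance <- function(assignments, family_lengths) {
  if (!nrow(assignments))
    return(functional_profile_df(character(0), character(0), numeric(0)))
  miss <- setdiff(unique(assignments$family), names(family_lengths))
  if (length(miss)) stop("missing family length: ",
                         paste(head(miss, 3L), collapse = ", "))
  key <- paste(assignments$family, assignments$stratum, sep = "\r")
  w <- tapply(assignments$weight, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  fam <- vapply(parts, `[[`, character(1), 1L)
  strat <- vapply(parts, `[[`, character(1), 2L)
  prof <- functional_profile_df(
    fam, strat, as.numeric(w) / (family_lengths[fam] / 1000))
  prof[order(prof$family, prof$stratum), , drop = FALSE]
}

#' Regroup a functional profile to broader features
#'
#' Target feature abundance is the sum of its member families'
#' abundances, per stratum.  A family mapping to several features (e.g.
#' several EC numbers) contributes its full abundance to each;
#' unannotated families are absent from the regrouped output.
#'
#' @param profile a functional profile.
#' @param feature_map data.frame `family`, `feature` (long format, one
#'   row per association).
#' @return functional profile over features, same units.
#' @export
regroup <- function(profile, feature_map) {
  m <- merge(profile, feature_map, by = "family")
  if (!nrow(m))
    return(functional_profile_df(character(0), character(0), numeric(0),
                                 units = attr(profile, "units")))
  key <- paste(m$feature, m$stratum, sep = "\r")
  w <- tapply(m$abundance, key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- functional_profile_df(
    vapply(parts, `[[`, character(1), 1L),
    vapply(parts, `[[`, character(1), 2L),
    as.numeric(w), units = attr(profile, "units"))
  out[order(out$family, out$stratum), , drop = FALSE]
}

#' Renormalize a profile to copies per million
#'
#' Scales the profile by one global factor so that the community totals
#' sum to 1e6; stratum/total ratios are unchanged.
#'
#' @param profile an RPK functional profile.
#' @return the profile in CPM units.
#' @export
renormalize_cpm <- function(profile) {
  total <- sum(profile$abundance)
  if (total <= 0) stop("all-zero profile cannot be renormalized")
  out <- profile
  out$abundance <- profile$abundance * 1e6 / total
  attr(out, "units") <- "CPM"
  out
}

#' Tiered functional profile of one sample
#'
#' Runs the full tiered search: nucleotide hits are coverage-filtered
#' and assigned ([coverage_filter()], [nucleotide_assign()]); reads left
#' unmapped fall through to the translated tier
#' ([translated_assign()], after a protein-level coverage filter);
#' per-family RPK abundances are computed with nucleotide-tier weight
#' stratified by the pangene's species and translated-tier weight under
#' `"unclassified"`.
#'
#' @param nuc_hits nucleotide hits: `read_id`, `target_id`, `start`,
#'   `end`, `score`.
#' @param pangene_info data.frame `target_id`, `family`,
#'   `species_taxid`, `length` (nt).
#' @param read_ids all read ids of the sample.
#' @param trans_hits translated hits for unmapped reads: `read_id`,
#'   `family_id`, `identity`, `score`, `start`, `end` (optional; NULL
#'   disables the tier).
#' @param protein_lengths named vector `family_id -> aa length` for the
#'   translated tier.
#' @param family_lengths named vector `family -> nt length` used for
#'   RPK; defaults to pangene family lengths plus `3 * protein_lengths`.
#' @param min_covered_fraction,min_identity,top_fraction,multi_hit_k
#'   tier parameters (defaults 0.5, 80, 0.01, 1).
#' @return list: `profile` (RPK functional profile), `read_fates`
#'   (counts: nucleotide, translated, unclassified, unmapped_input).
#' @export
functional_profile <- function(nuc_hits, pangene_info, read_ids,
                               trans_hits = NULL, protein_lengths = NULL,
                               family_lengths = NULL,
                               min_covered_fraction = 0.5,
                               min_identity = 80, top_fraction = 0.01,
                               multi_hit_k = 1L) {
  plen <- setNames(pangene_info$length, pangene_info$target_id)
  surv <- coverage_filter(nuc_hits, plen, min_covered_fraction)
  nuc <- nucleotide_assign(surv, read_ids, multi_hit_k)

  idx <- match(nuc$assignments$target_id, pangene_info$target_id)
  nuc_asn <- data.frame(
    family = pangene_info$family[idx],
    stratum = as.character(pangene_info$species_taxid[idx]),
    weight = nuc$assignments$weight, stringsAsFactors = FALSE)

  trans_asn <- data.frame(family = character(0), stratum = character(0),
                          weight = numeric(0))
  n_trans_reads <- 0L
  if (!is.null(trans_hits) && nrow(trans_hits)) {
    th <- trans_hits[trans_hits$read_id %in% nuc$unmapped, , drop = FALSE]
    if (!is.null(protein_lengths) && all(c("start", "end") %in% names(th))) {
      th$target_id <- th$family_id
      th <- coverage_filter(th, protein_lengths, min_covered_fraction)
    }
    ta <- translated_assign(th, min_identity, top_fraction)
    n_trans_reads <- length(unique(ta$read_id))
    trans_asn <- data.frame(family = ta$family_id,
                            stratum = "unclassified",
                            weight = ta$weight, stringsAsFactors = FALSE)
  }

  if (is.null(family_lengths)) {
    fam_nt <- tapply(pangene_info$length, pangene_info$family, mean)
    family_lengths <- setNames(as.numeric(fam_nt), names(fam_nt))
    if (!is.null(protein_lengths))
      family_lengths <- c(family_lengths,
                          3 * protein_lengths[setdiff(names(protein_lengths),
                                                      names(family_lengths))])
  }
  prof <- family_abundance(rbind(nuc_asn, trans_asn), family_lengths)

  n_nuc_reads <- length(unique(nuc$assignments$read_id))
  list(profile = prof,
       read_fates = c(nucleotide = n_nuc_reads,
                      translated = n_trans_reads,
                      unclassified = length(nuc$unmapped) - n_trans_reads,
                      total = length(read_ids)))
}

#' Gold-standard functional profile of a simulated community
#'
#' The expected abundance of a family is the sum over community genomes
#' of the genome's mean coverage depth times the family's gene copy
#' number in that genome (depth-copies units, length-consistent with
#' the RPK profile up to the global reads-per-kilobase factor).
#'
#' @param genomes list of [genome_record()] objects in the community.
#' @param genome_depths named numeric vector `genome_id -> mean depth`.
#' @return data.frame `family`, `abundance`.
#' @export
gold_standard_functional <- function(genomes, genome_depths) {
  rows <- lapply(genomes, function(g) {
    d <- genome_depths[[g$genome_id]] %||% 0
    if (d == 0 || !nrow(g$genes)) return(NULL)
    copies <- table(g$genes$family90)
    data.frame(family = names(copies),
               abundance = d * as.numeric(copies),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(family = character(0), abundance = numeric(0)))
  tot <- tapply(rows$abundance, rows$family, sum)
  data.frame(family = names(tot), abundance = as.numeric(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}
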