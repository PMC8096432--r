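# Taxonomy-table helpers.  A taxonomy is a plain data.frame with columns
# taxid, parent_taxid (NA at the root), rank, name, avg_genome_length
# (nt; NA for internal clades).  Ranks follow the standard seven-level
# ladder; paths are rendered with the conventional one-letter prefixes
# (k__, p__, c__, o__, f__, g__, s__).

RANK_ORDER <- c("kingdom", "phylum", "class", "order",
                "family", "genus", "species")
RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__",
                 order = "o__", family = "f__", genus = "g__",
                 species = "s__")

validate_taxonomy <- function(taxonomy) {
  need <- c("taxid", "parent_taxid", "rank", "name", "avg_genome_length")
  miss <- setdiff(need, names(taxonomy))
  if (length(miss)) stop("taxonomy missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(taxonomy$taxid)) stop("duplicated taxids in taxonomy")
  if (any(!taxonomy$rank %in% RANK_ORDER))
    stop("unknown rank(s): ",
         paste(setdiff(taxonomy$rank, RANK_ORDER), collapse = ", "))
  invisible(taxonomy)
}

# Root-to-clade chain of row indices for one taxid.
taxonomy_chain <- function(taxonomy, taxid) {
  idx <- match(taxid, taxonomy$taxid)
  if (is.na(idx)) stop("taxid ", taxid, " missing from taxonomy")
  chain <- idx
  while (!is.na(taxonomy$parent_taxid[idx])) {
    idx <- match(taxonomy$parent_taxid[idx], taxonomy$taxid)
    if (is.na(idx)) stop("broken parent link in taxonomy")
    chain <- c(idx, chain)
  }
  chain
}

#' Rank-prefixed lineage paths for every clade of a taxonomy
#'
#' @param taxonomy taxonomy data.frame (see [simulate_taxonomy()]).
#' @return data.frame with `taxid`, `rank`, `taxonomy_path` (e.g.
#'   `"k__Bacteria|...|s__Genus_species"`) and the parallel pipe-joined
#'   `taxid_path`.
#' @export
taxonomy_paths <- function(taxonomy) {
  validate_taxonomy(taxonomy)
  chains <- lapply(taxonomy$taxid, taxonomy_chain, taxonomy = taxonomy)
  data.frame(
    taxid = taxonomy$taxid,
    rank = taxonomy$rank,
    taxonomy_path = vapply(chains, function(ch)
      paste0(RANK_PREFIX[taxonomy$rank[ch]], taxonomy$name[ch],
             collapse = "|"), character(1)),
    taxid_path = vapply(chains, function(ch)
      paste(taxonomy$taxid[ch], collapse = "|"), character(1)),
    stringsAsFactors = FALSE)
}

# All descendant species taxids of each clade (including itself when the
# clade is a species); returns a named list keyed by as.character(taxid).
species_descendants <- function(taxonomy) {
  paths <- lapply(taxonomy$taxid, taxonomy_chain, taxonomy = taxonomy)
  species_idx <- which(taxonomy$rank == "species")
  out <- lapply(seq_len(nrow(taxonomy)), function(i) {
    keep <- vapply(paths[species_idx], function(ch) i %in% ch, logical(1))
    taxonomy$taxid[species_idx[keep]]
  })
  names(out) <- as.character(taxonomy$taxid)
  out
}
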