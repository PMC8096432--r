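# Fixture builders used across the suite.  Everything is generated in
# code under fixed seeds; no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Genomes of one species from an explicit family x genome membership
# matrix, so that coreness and tier bands can be controlled exactly.
make_species_genomes <- function(species_taxid, membership,
                                 seqs = NULL, fam90 = NULL, fam50 = NULL,
                                 spacer = 60L, seed = 1L) {
  set.seed(seed)
  n_fam <- nrow(membership)
  n_gen <- ncol(membership)
  fam90 <- fam90 %||% sprintf("F%d_%03d", species_taxid, seq_len(n_fam))
  fam50 <- fam50 %||% sub("^F", "P", fam90)
  if (is.null(seqs)) seqs <- random_gene_seqs(n_fam, seed = seed + 1L)
  lapply(seq_len(n_gen), function(gi) {
    gid <- sprintf("G%d_%02d", species_taxid, gi)
    present <- which(membership[, gi])
    pieces <- character(0)
    genes <- list()
    pos <- 0L
    for (i in present) {
      sp <- paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
                  collapse = "")
      pos <- pos + spacer
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("%s__%s", gid, fam90[i]), contig = "c1",
        start = pos, end = pos + nchar(seqs[i]), strand = "+",
        protein_len = nchar(seqs[i]) %/% 3L,
        family90 = fam90[i], family50 = fam50[i],
        stringsAsFactors = FALSE)
      pieces <- c(pieces, sp, seqs[i])
      pos <- pos + nchar(seqs[i])
    }
    genome_record(gid, species_taxid,
                  c(c1 = paste(c(pieces, "ACGTACGT"), collapse = "")),
                  do.call(rbind, genes))
  })
}

random_gene_seqs <- function(n, len = 450L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# Alignment rows in the pileup schema for one marker, from explicit
# per-read sequences placed at explicit offsets.
make_pileup_alignments <- function(marker_id, seqs, starts, qual = 40L) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
             marker_id = marker_id, mapq = 42L,
             read_length = nchar(seqs),
             aligned_start = starts, aligned_end = starts + nchar(seqs),
             seq_on_target = seqs,
             qual_on_target = vapply(nchar(seqs), function(n)
               strrep(intToUtf8(qual + 33L), n), character(1)),
             stringsAsFactors = FALSE)
}

# Random taxonomic profile for format fuzzing.
random_profile <- function(n_species = 4L, seed = 1L) {
  set.seed(seed)
  u <- simulate_universe(n_species, genomes_per_species = 1L,
                         n_core = 1L, seed = seed)
  tax <- u$taxonomy
  tax$avg_genome_length[tax$rank == "species"] <- 1e6
  cov <- setNames(runif(n_species, 0.1, 5),
                  as.character(10000L + seq_len(n_species)))
  prof <- relative_abundance(aggregate_taxonomy(cov, tax))
  paths <- taxonomy_paths(tax)
  i <- match(prof$taxid, paths$taxid)
  out <- data.frame(taxid = prof$taxid, rank = prof$rank,
                    taxonomy_path = paths$taxonomy_path[i],
                    taxid_path = paths$taxid_path[i],
                    relative_abundance = prof$relative_abundance,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$rank, c("kingdom", "phylum", "class", "order",
                                     "family", "genus", "species")),
                   out$taxonomy_path), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tax_profile", "data.frame"),
            unknown_fraction = round(runif(1, 0, 30), 4),
            total_reads = NA_integer_, species_coverage = numeric(0))
}
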