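# Deterministic synthetic data: taxonomies, species pangenomes, strain
# genomes, communities and shotgun reads with gold-standard truths.  All
# randomness flows from the explicit `seed` arguments so that repeated
# builds are byte-identical.

#' Synthetic taxonomy for a set of species
#'
#' Builds a seven-rank taxonomy (kingdom to species) covering
#' `n_species` species: one kingdom, two phyla (each with its own
#' class/order/family chain) and one genus per two species, so that
#' clade aggregation is exercised at every rank.  Species taxids are
#' `10000 + i`.
#'
#' @param n_species number of species (>= 1).
#' @param species_names optional character vector of names; defaults to
#'   `Genus_i_species_j` style binomials.
#' @return taxonomy data.frame: `taxid`, `parent_taxid`, `rank`, `name`,
#'   `avg_genome_length` (NA until genomes exist; see
#'   [simulate_universe()]).
#' @export
simulate_taxonomy <- function(n_species, species_names = NULL) {
  stopifnot(n_species >= 1L)
  n_genus <- ceiling(n_species / 2)
  genus_of <- ceiling(seq_len(n_species) / 2)
  phylum_of_genus <- ifelse(seq_len(n_genus) %% 2 == 1L, 1L, 2L)
  n_phyla <- length(unique(phylum_of_genus))
  if (is.null(species_names))
    species_names <- sprintf("Genus%d_species%d", genus_of,
                             seq_len(n_species))
  stopifnot(length(species_names) == n_species)

  rows <- list(data.frame(taxid = 2L, parent_taxid = NA_integer_,
                          rank = "kingdom", name = "Bacteria",
                          stringsAsFactors = FALSE))
  for (p in seq_len(n_phyla)) {
    rows <- c(rows, list(data.frame(
      taxid = c(1000L, 2000L, 3000L, 4000L) + p,
      parent_taxid = c(2L, 1000L + p, 2000L + p, 3000L + p),
      rank = c("phylum", "class", "order", "family"),
      name = sprintf(c("Phylum%d", "Class%d", "Order%d", "Family%d"), p),
      stringsAsFactors = FALSE)))
  }
  for (g in seq_len(n_genus)) {
    rows <- c(rows, list(data.frame(
      taxid = 5000L + g, parent_taxid = 4000L + phylum_of_genus[g],
      rank = "genus", name = sprintf("Genus%d", g),
      stringsAsFactors = FALSE)))
  }
  rows <- c(rows, list(data.frame(
    taxid = 10000L + seq_len(n_species),
    parent_taxid = 5000L + genus_of,
    rank = "species", name = species_names, stringsAsFactors = FALSE)))
  tax <- do.call(rbind, rows)
  tax$avg_genome_length <- NA_real_
  tax
}

#' Simulate one species pangenome
#'
#' Generates `n_genomes` genomes of one species sharing `n_core` core
#' gene families (present in every genome) and `n_accessory` accessory
#' families, each present in a random non-empty subset of genomes
#' (inclusion probability `accessory_prob`).  Family nucleotide
#' sequences are random DNA, identical across member genomes; each
#' genome is a single contig of genes separated by random spacers, with
#' random gene strands.  Gene lengths are drawn uniformly (in codons)
#' from `gene_len_range` and each 90% family maps 1:1 to a 50% family
#' unless `family50_of` overrides it.  `extra_families` (a data.frame
#' with `family90`, `family50`, `seq`) are appended to every genome and
#' can be shared across species to create quasi-markers.
#'
#' @param species_taxid species taxid for all genomes.
#' @param n_genomes,n_core,n_accessory layout counts.
#' @param gene_len_range nucleotide length range, rounded to codons
#'   (default 450-1500 nt, i.e. 150-500 aa).
#' @param spacer_len_range intergenic spacer length range (default
#'   100-300 nt).
#' @param accessory_prob per-genome inclusion probability of an
#'   accessory family (default 0.5; at least one genome always carries
#'   it).
#' @param family_prefix prefix for family ids (default
#'   `"F<taxid>_"`).
#' @param family50_of optional named map `family90 -> family50`.
#' @param extra_families optional data.frame of families shared with
#'   other species.
#' @param seed RNG seed.
#' @return list: `genomes` (list of [genome_record()]), `families`
#'   (data.frame `family90`, `family50`, `seq`, `core`, `member_genomes`
#'   list column).
#' @export
simulate_pangenome <- function(species_taxid, n_genomes = 3L, n_core = 30L,
                               n_accessory = 0L,
                               gene_len_range = c(450L, 1500L),
                               spacer_len_range = c(100L, 300L),
                               accessory_prob = 0.5,
                               family_prefix = NULL,
                               family50_of = NULL,
                               extra_families = NULL, seed = 1L) {
  if (n_core + n_accessory + NROW(extra_families) < 1L)
    stop("pangenome must contain at least one family")
  set.seed(seed)
  family_prefix <- family_prefix %||% sprintf("F%d_", species_taxid)

  n_fam <- n_core + n_accessory
  fam90 <- sprintf("%s%03d", family_prefix, seq_len(n_fam))
  fam50 <- if (is.null(family50_of)) sub("^F", "P", fam90) else
    unname(family50_of[fam90])
  codons <- round(runif(n_fam, gene_len_range[1L] / 3,
                        gene_len_range[2L] / 3))
  seqs <- vapply(codons * 3L, random_dna, character(1))
  core <- rep(c(TRUE, FALSE), c(n_core, n_accessory))
  if (!is.null(extra_families)) {
    fam90 <- c(fam90, extra_families$family90)
    fam50 <- c(fam50, extra_families$family50)
    seqs <- c(seqs, extra_families$seq)
    core <- c(core, rep(TRUE, nrow(extra_families)))
  }

  membership <- lapply(seq_along(fam90), function(i) {
    if (core[i]) return(seq_len(n_genomes))
    inc <- which(runif(n_genomes) < accessory_prob)
    if (!length(inc)) inc <- sample.int(n_genomes, 1L)
    inc
  })

  genomes <- lapply(seq_len(n_genomes), function(gi) {
    gid <- sprintf("G%d_%02d", species_taxid, gi)
    present <- which(vapply(membership, function(m) gi %in% m, logical(1)))
    strands <- sample(c("+", "-"), length(present), replace = TRUE)
    pieces <- character(0)
    genes <- vector("list", length(present))
    pos <- 0L
    for (k in seq_along(present)) {
      i <- present[k]
      spacer <- random_dna(round(runif(1, spacer_len_range[1L],
                                       spacer_len_range[2L])))
      pos <- pos + nchar(spacer)
      gseq <- if (strands[k] == "-") revcomp(seqs[i]) else seqs[i]
      genes[[k]] <- data.frame(
        gene_id = sprintf("%s__%s", gid, fam90[i]),
        contig = "c1", start = pos, end = pos + nchar(gseq),
        strand = strands[k], protein_len = nchar(gseq) %/% 3L,
        family90 = fam90[i], family50 = fam50[i],
        stringsAsFactors = FALSE)
      pieces <- c(pieces, spacer, gseq)
      pos <- pos + nchar(gseq)
    }
    tail_spacer <- random_dna(round(runif(1, spacer_len_range[1L],
                                          spacer_len_range[2L])))
    contig <- paste(c(pieces, tail_spacer), collapse = "")
    genome_record(gid, species_taxid, c(c1 = contig),
                  do.call(rbind, genes))
  })

  fam_df <- data.frame(family90 = fam90, family50 = fam50, seq = seqs,
                       core = core, stringsAsFactors = FALSE)
  fam_df$member_genomes <- lapply(membership, function(m)
    sprintf("G%d_%02d", species_taxid, m))
  list(genomes = genomes, families = fam_df)
}

#' Simulate a multi-species universe of genomes
#'
#' Generates a taxonomy and one pangenome per species, with disjoint
#' family ids except for `n_shared` families that each pair of
#' consecutive species shares (creating quasi-marker candidates).
#' Fills `avg_genome_length` in the taxonomy from the generated genomes.
#'
#' @param n_species number of species.
#' @param genomes_per_species integer scalar or vector.
#' @param n_core,n_accessory per-species family counts.
#' @param n_shared families shared between species `2i - 1` and `2i`.
#' @param seed RNG seed; per-species seeds are derived from it.
#' @param ... forwarded to [simulate_pangenome()].
#' @return list: `genomes` (flat list), `taxonomy`, `pangenomes` (per
#'   species simulation results, named by taxid).
#' @export
simulate_universe <- function(n_species, genomes_per_species = 3L,
                              n_core = 30L, n_accessory = 0L,
                              n_shared = 0L, seed = 1L, ...) {
  taxonomy <- simulate_taxonomy(n_species)
  ngen <- rep_len(genomes_per_species, n_species)
  taxids <- 10000L + seq_len(n_species)

  shared <- NULL
  if (n_shared > 0L) {
    set.seed(seed * 1000L + 999L)
    shared <- data.frame(
      family90 = sprintf("FSH_%03d", seq_len(n_shared)),
      family50 = sprintf("PSH_%03d", seq_len(n_shared)),
      seq = vapply(rep(600L, n_shared), random_dna, character(1)),
      stringsAsFactors = FALSE)
  }

  sims <- lapply(seq_len(n_species), function(i) {
    extra <- if (!is.null(shared) && i <= 2L) shared else NULL
    simulate_pangenome(taxids[i], n_genomes = ngen[i], n_core = n_core,
                       n_accessory = n_accessory, extra_families = extra,
                       seed = seed * 1000L + i, ...)
  })
  names(sims) <- as.character(taxids)

  genomes <- unlist(lapply(sims, `[[`, "genomes"), recursive = FALSE)
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")

  glen <- vapply(genomes, function(g) sum(nchar(g$contigs)), numeric(1))
  gsp <- vapply(genomes, function(g) g$species_taxid, integer(1))
  avg <- tapply(glen, gsp, mean)
  taxonomy$avg_genome_length[match(as.integer(names(avg)),
                                   taxonomy$taxid)] <- as.numeric(avg)
  list(genomes = genomes, taxonomy = taxonomy, pangenomes = sims)
}

#' Log-normal community abundances
#'
#' Draws per-species relative cell abundances from a log-normal
#' distribution and sum-normalizes them to 1.
#'
#' @param species_taxids species taxids.
#' @param meanlog,sdlog log-normal parameters (defaults 0 and 1).
#' @param seed RNG seed.
#' @return named numeric vector summing to 1.
#' @export
simulate_community <- function(species_taxids, meanlog = 0, sdlog = 1,
                               seed = 1L) {
  set.seed(seed)
  a <- rlnorm(length(species_taxids), meanlog, sdlog)
  setNames(a / sum(a), as.character(species_taxids))
}

# Phred+33 quality string for a constant per-base error rate.
phred_string <- function(n, error_rate) {
  q <- if (error_rate <= 0) 40L else
    min(40L, max(2L, round(-10 * log10(error_rate))))
  strrep(intToUtf8(q + 33L), n)
}

#' Simulate shotgun reads from a community
#'
#' Each read is drawn from one source genome with probability
#' proportional to `abundance * genome_length` (read-fraction sampling),
#' from a uniform start position and a random strand, with independent
#' substitution errors at `error_rate`.  One genome per species acts as
#' the community strain: by default the lexicographically first genome
#' of the species, overridable via `strain_of`.  Two gold-standard
#' relative abundance scales are recorded: the read fraction (proportional
#' to `abundance * length`) and the coverage/cell fraction
#' (proportional to `abundance`).
#'
#' @param genomes list of [genome_record()] objects (>= 1 per species).
#' @param abundances named vector from [simulate_community()].
#' @param n_reads total reads.
#' @param read_len read length (default 150 nt).
#' @param error_rate per-base substitution probability (default 0).
#' @param paired emit mate pairs from opposite strands (default FALSE;
#'   mates share a fragment of `insert_len` nt).
#' @param insert_len fragment length for paired mode (default 450).
#' @param strain_of optional named map `taxid -> genome_id`.
#' @param seed RNG seed.
#' @return list: `reads` (data.frame `read_id`, `genome_id`, `contig`,
#'   `start`, `end`, `strand`, `seq`, `qual`), `gold_read_fraction` and
#'   `gold_coverage_fraction` (named percent vectors summing to 100),
#'   `spec` (the simulation parameters).
#' @export
simulate_reads <- function(genomes, abundances, n_reads, read_len = 150L,
                           error_rate = 0, paired = FALSE,
                           insert_len = 450L, strain_of = NULL, seed = 1L) {
  stopifnot(abs(sum(abundances) - 1) < 1e-8)
  set.seed(seed)
  if (n_reads < length(abundances))
    warning("fewer reads than species; some species will be unsampled")

  gsp <- vapply(genomes, function(g) g$species_taxid, integer(1))
  gids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- gids
  taxids <- names(abundances)
  strain <- vapply(taxids, function(t) {
    if (!is.null(strain_of) && t %in% names(strain_of))
      return(strain_of[[t]])
    sort(gids[gsp == as.integer(t)])[1L]
  }, character(1))
  glen <- vapply(strain, function(g)
    sum(nchar(genomes[[g]]$contigs)), numeric(1))

  w <- abundances * glen
  counts <- as.vector(stats::rmultinom(1L, n_reads, w))
  frag_len <- if (paired) insert_len else read_len

  rows <- vector("list", length(taxids))
  for (i in seq_along(taxids)) {
    if (counts[i] == 0L) next
    g <- genomes[[strain[i]]]
    clen <- nchar(g$contigs)
    ctg <- names(clen)[sample.int(length(clen), counts[i], replace = TRUE,
                                  prob = clen)]
    start <- floor(runif(counts[i]) * (clen[ctg] - frag_len + 1L))
    strand <- sample(c("+", "-"), counts[i], replace = TRUE)
    rows[[i]] <- data.frame(genome_id = g$genome_id, contig = ctg,
                            start = as.integer(start), strand = strand,
                            stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, rows)
  rownames(frags) <- NULL
  n <- nrow(frags)

  extract <- function(frag_start, mate) {
    # mate 1 reads the fragment 5' end on `strand`; mate 2 the other end
    if (mate == 1L) {
      fwd_start <- ifelse(frags$strand == "+", frag_start,
                          frag_start + frag_len - read_len)
      out_strand <- frags$strand
    } else {
      fwd_start <- ifelse(frags$strand == "+",
                          frag_start + frag_len - read_len, frag_start)
      out_strand <- ifelse(frags$strand == "+", "-", "+")
    }
    seqs <- character(n)
    for (j in seq_len(n)) {
      g <- genomes[[frags$genome_id[j]]]
      s <- substr(g$contigs[[frags$contig[j]]], fwd_start[j] + 1L,
                  fwd_start[j] + read_len)
      if (error_rate > 0) {
        ch <- seq_chars(s)
        err <- which(runif(read_len) < error_rate)
        if (length(err)) {
          ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(DNA_BASES, b), 1L), character(1))
          s <- paste(ch, collapse = "")
        }
      }
      if (out_strand[j] == "-") s <- revcomp(s)
      seqs[j] <- s
    }
    data.frame(read_id = sprintf("r%06d/%d", seq_len(n), mate),
               genome_id = frags$genome_id, contig = frags$contig,
               start = as.integer(fwd_start),
               end = as.integer(fwd_start + read_len),
               strand = out_strand, seq = seqs,
               qual = phred_string(read_len, error_rate),
               stringsAsFactors = FALSE)
  }

  reads <- extract(frags$start, 1L)
  if (paired) reads <- rbind(reads, extract(frags$start, 2L))

  gold_reads <- 100 * w / sum(w)
  gold_cov <- 100 * abundances / sum(abundances)
  list(reads = reads,
       gold_read_fraction = gold_reads,
       gold_coverage_fraction = gold_cov,
       spec = list(n_reads = n_reads, read_len = read_len,
                   error_rate = error_rate, paired = paired,
                   seed = seed, strain_of = strain))
}

#' Derive a strain genome from a base genome
#'
#' The strain is the base genome with `drop_families` gene families
#' deleted (the gene interval is excised and coordinates rebuilt) and
#' `n_snvs` substitutions placed at distinct random positions inside the
#' bodies of the retained genes.
#'
#' @param base_genome a [genome_record()].
#' @param n_snvs number of SNVs (default 0).
#' @param drop_families character vector of `family90` ids to delete.
#' @param suffix appended to the genome id (default `"_strain"`).
#' @param seed RNG seed.
#' @return list: `genome` (new [genome_record()]), `snvs` (data.frame
#'   `contig`, `pos` 0-based in the strain genome, `gene_id`,
#'   `offset_in_gene` on the gene's forward frame, `ref`, `alt`),
#'   `dropped_families`.
#' @export
simulate_strain <- function(base_genome, n_snvs = 0L,
                            drop_families = character(0),
                            suffix = "_strain", seed = 1L) {
  set.seed(seed)
  genes <- base_genome$genes
  drop <- genes$family90 %in% drop_families
  contigs <- base_genome$contigs

  new_contigs <- contigs
  new_genes <- genes[!drop, , drop = FALSE]
  for (ctg in names(contigs)) {
    del <- genes[drop & genes$contig == ctg, , drop = FALSE]
    if (!nrow(del)) next
    del <- del[order(del$start), ]
    s <- contigs[[ctg]]
    kept <- character(0)
    cursor <- 0L
    for (j in seq_len(nrow(del))) {
      kept <- c(kept, substr(s, cursor + 1L, del$start[j]))
      cursor <- del$end[j]
    }
    kept <- c(kept, substr(s, cursor + 1L, nchar(s)))
    new_contigs[[ctg]] <- paste(kept, collapse = "")
    # shift retained gene coordinates on this contig
    on_ctg <- new_genes$contig == ctg
    shift <- vapply(new_genes$start[on_ctg], function(p)
      sum(del$end[del$end <= p] - del$start[del$end <= p]), integer(1))
    new_genes$start[on_ctg] <- new_genes$start[on_ctg] - shift
    new_genes$end[on_ctg] <- new_genes$end[on_ctg] - shift
  }

  snvs <- data.frame(contig = character(0), pos = integer(0),
                     gene_id = character(0), offset_in_gene = integer(0),
                     ref = character(0), alt = character(0),
                     stringsAsFactors = FALSE)
  if (n_snvs > 0L) {
    body_len <- new_genes$end - new_genes$start
    if (n_snvs > sum(body_len)) stop("more SNVs than gene positions")
    flat <- sample.int(sum(body_len), n_snvs)
    cum <- cumsum(body_len)
    gene_idx <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = FALSE)
    offset <- flat - c(0L, cum)[gene_idx] - 1L
    pos <- new_genes$start[gene_idx] + offset
    ctg <- new_genes$contig[gene_idx]
    ref <- substring(vapply(ctg, function(cc) new_contigs[[cc]],
                            character(1)), pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1))
    for (j in seq_len(n_snvs))
      substr(new_contigs[[ctg[j]]], pos[j] + 1L, pos[j] + 1L) <- alt[j]
    fwd_off <- ifelse(new_genes$strand[gene_idx] == "+", offset,
                      body_len[gene_idx] - 1L - offset)
    snvs <- data.frame(contig = ctg, pos = as.integer(pos),
                       gene_id = new_genes$gene_id[gene_idx],
                       offset_in_gene = as.integer(fwd_off),
                       ref = unname(ref), alt = unname(alt),
                       stringsAsFactors = FALSE)
    snvs <- snvs[order(snvs$contig, snvs$pos), , drop = FALSE]
    rownames(snvs) <- NULL
  }

  g <- genome_record(paste0(base_genome$genome_id, suffix),
                     base_genome$species_taxid, new_contigs, new_genes)
  list(genome = g, snvs = snvs,
       dropped_families = unique(genes$family90[drop]))
}

#' Simulate a cohort of subjects carrying private strains
#'
#' Every subject carries a private strain of the base genome
#' (`n_snvs` substitutions each, distinct random placements); each of
#' the `n_pairs` transmission pairs consists of two subjects sharing an
#' identical strain.  Sample metadata and the related-pair truth table
#' are emitted in the layout [infer_transmission()] expects.
#'
#' @param base_genome a [genome_record()].
#' @param n_unrelated number of unrelated subjects.
#' @param n_pairs number of transmission pairs (two subjects each).
#' @param n_snvs SNVs per strain (default 30).
#' @param seed RNG seed.
#' @return list: `strains` (named list `sample_id -> genome_record`),
#'   `metadata` (data.frame `sample_id`, `subject_id`,
#'   `collection_date`), `related_pairs` (data.frame `sample_a`,
#'   `sample_b`).
#' @export
simulate_strain_cohort <- function(base_genome, n_unrelated = 40L,
                                   n_pairs = 10L, n_snvs = 30L, seed = 1L) {
  n_strains <- n_unrelated + n_pairs
  strains <- lapply(seq_len(n_strains), function(i)
    simulate_strain(base_genome, n_snvs = n_snvs,
                    suffix = sprintf("_st%02d", i),
                    seed = seed * 1000L + i)$genome)

  samples <- list()
  meta <- list()
  pairs <- list()
  for (i in seq_len(n_unrelated)) {
    sid <- sprintf("S%02d", i)
    samples[[sid]] <- strains[[i]]
    meta[[sid]] <- data.frame(sample_id = sid,
                              subject_id = sprintf("subj%02d", i),
                              collection_date = "2020-01-01",
                              stringsAsFactors = FALSE)
  }
  for (p in seq_len(n_pairs)) {
    a <- sprintf("T%02da", p); b <- sprintf("T%02db", p)
    samples[[a]] <- strains[[n_unrelated + p]]
    samples[[b]] <- strains[[n_unrelated + p]]
    meta[[a]] <- data.frame(sample_id = a,
                            subject_id = sprintf("pairsubj%02da", p),
                            collection_date = "2020-01-01",
                            stringsAsFactors = FALSE)
    meta[[b]] <- data.frame(sample_id = b,
                            subject_id = sprintf("pairsubj%02db", p),
                            collection_date = "2020-01-01",
                            stringsAsFactors = FALSE)
    pairs[[p]] <- data.frame(sample_a = a, sample_b = b,
                             stringsAsFactors = FALSE)
  }
  list(strains = samples,
       metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
       related_pairs = if (length(pairs))
         do.call(rbind, pairs) else
           data.frame(sample_a = character(0), sample_b = character(0)))
}
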