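# Marker database construction: species pangenomes from annotated
# genomes, per-family coreness/uniqueness statistics, and tiered
# selection of species-specific marker genes.

#' Construct a genome record
#'
#' Bundles one annotated genome: its contig sequences and its gene table.
#' Gene coordinates are 0-based half-open on the forward strand of the
#' contig; genes on the minus strand are extracted as the reverse
#' complement of the slice.  Each gene belongs to exactly one gene family
#' at each of the two clustering tiers (a 90%-identity family nested
#' inside a 50%-identity family).
#'
#' @param genome_id unique identifier (string).
#' @param species_taxid integer NCBI-style species taxid.
#' @param contigs named character vector of contig sequences.
#' @param genes data.frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand` ("+"/"-"), `protein_len` (amino acids), `family90`,
#'   `family50`.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, species_taxid, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            length(species_taxid) == 1L,
            is.character(contigs), !is.null(names(contigs)),
            is.data.frame(genes))
  need <- c("gene_id", "contig", "start", "end", "strand",
            "protein_len", "family90", "family50")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(genes)) {
    if (any(!genes$contig %in% names(contigs)))
      stop("gene on unknown contig")
    clen <- nchar(contigs)[genes$contig]
    if (any(genes$start < 0L) || any(genes$end <= genes$start) ||
        any(genes$end > clen))
      stop("gene coordinates out of contig bounds")
    if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  }
  structure(list(genome_id = genome_id,
                 species_taxid = as.integer(species_taxid),
                 contigs = contigs, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s  species %d  %d contig(s), %d gene(s)>\n",
              x$genome_id, x$species_taxid, length(x$contigs),
              nrow(x$genes)))
  invisible(x)
}

# Nucleotide sequence of one gene row within a genome record.
gene_sequence <- function(genome, gene_row) {
  s <- substr(genome$contigs[[gene_row$contig]],
              gene_row$start + 1L, gene_row$end)
  if (gene_row$strand == "-") s <- revcomp(s)
  s
}

#' Flag low-quality species names
#'
#' Species whose names indicate provisional, unidentified or otherwise
#' weakly defined taxa (e.g. `Candidatus` taxa, `..._sp_...` binomials,
#' unnamed `bacterium` entries) are flagged so that they can be excluded
#' from the species-level uniqueness statistics.  Matching is
#' case-sensitive and operates on underscore-separated names.
#'
#' @param species_name character vector of underscore-separated names.
#' @return logical vector, `TRUE` where the name is low quality.
#' @examples
#' flag_low_quality_species(c("Candidatus_Foo_bar", "Ruminococcus_bromii",
#'                            "Clostridium_sp_ABC"))
#' @export
flag_low_quality_species <- function(species_name) {
  stopifnot(is.character(species_name))
  clauses <- c(
    "(C|c)andidat(e|us)",
    "_sp(_.*|$)",
    "(.*_|^)(b|B)acterium(_.*|)",
    ".*(eury|)archaeo(n_|te|n$).*",
    ".*(endo|)symbiont.*",
    ".*genomosp_.*",
    ".*unidentified.*",
    ".*_bacteria_.*",
    ".*_taxon_.*",
    ".*_et_al_.*",
    ".*_and_.*",
    ".*(cyano|proteo|actinobacterium_.*)")
  out <- rep(FALSE, length(species_name))
  ok <- !is.na(species_name) & nzchar(species_name)
  if (any(ok)) {
    pat <- paste0("(", paste(clauses, collapse = ")|("), ")")
    out[ok] <- grepl(pat, species_name[ok], perl = TRUE)
  }
  out
}

#' Build a species pangenome
#'
#' The pangenome is the union of 90%-identity gene families observed in
#' any genome of the species.  One representative gene is chosen per
#' family deterministically: the member gene from the lexicographically
#' smallest genome id, breaking ties by longest nucleotide sequence and
#' then by gene id, so that repeated builds are identical.
#'
#' @param genomes list of [genome_record()] objects, all of one species.
#' @return an object of class `pangenome`: species taxid, genome ids and
#'   a per-family table (`families`) with representative sequence and
#'   membership.
#' @export
build_pangenome <- function(genomes) {
  if (length(genomes) == 0L) stop("no genomes")
  taxids <- vapply(genomes, function(g) g$species_taxid, integer(1))
  if (length(unique(taxids)) != 1L)
    stop("mixed species taxids: ", paste(unique(taxids), collapse = ", "))
  genome_ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(genome_ids)) stop("duplicated genome ids")
  names(genomes) <- genome_ids

  all_genes <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    cbind(g$genes, genome_id = g$genome_id, stringsAsFactors = FALSE)
  }))
  if (is.null(all_genes) || !nrow(all_genes)) stop("no genes in genomes")
  rownames(all_genes) <- NULL
  all_genes$nt_len <- all_genes$end - all_genes$start

  fam_ids <- sort(unique(all_genes$family90))
  families <- lapply(fam_ids, function(f) {
    sub <- all_genes[all_genes$family90 == f, , drop = FALSE]
    o <- order(sub$genome_id, -sub$nt_len, sub$gene_id, method = "radix")
    rep <- sub[o[1L], ]
    rep_seq <- gene_sequence(genomes[[rep$genome_id]], rep)
    list(family90 = f,
         family50 = rep$family50,
         rep_gene = rep$gene_id,
         rep_genome = rep$genome_id,
         rep_seq = rep_seq,
         rep_len = nchar(rep_seq),
         rep_protein_len = rep$protein_len,
         member_genes = sub$gene_id,
         member_genomes = sort(unique(sub$genome_id)))
  })
  fam_df <- data.frame(
    family90 = fam_ids,
    family50 = vapply(families, `[[`, character(1), "family50"),
    rep_gene = vapply(families, `[[`, character(1), "rep_gene"),
    rep_genome = vapply(families, `[[`, character(1), "rep_genome"),
    rep_seq = vapply(families, `[[`, character(1), "rep_seq"),
    rep_len = vapply(families, `[[`, integer(1), "rep_len"),
    rep_protein_len = vapply(families, function(x)
      as.integer(x$rep_protein_len), integer(1)),
    n_member_genomes = vapply(families, function(x)
      length(x$member_genomes), integer(1)),
    stringsAsFactors = FALSE)
  fam_df$member_genes <- setNames(lapply(families, `[[`, "member_genes"),
                                  fam_ids)
  fam_df$member_genomes <- setNames(
    lapply(families, `[[`, "member_genomes"), fam_ids)
  rownames(fam_df) <- fam_df$family90

  structure(list(species_taxid = taxids[[1L]],
                 genome_ids = sort(genome_ids),
                 n_genomes = length(genomes),
                 families = fam_df),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome species %d  %d genome(s), %d familie(s)>\n",
              x$species_taxid, x$n_genomes, nrow(x$families)))
  invisible(x)
}

# Long occurrence table (species, genome, family90, family50), one row
# per genome x family, across a list of pangenomes.
family_occurrences <- function(pangenomes) {
  do.call(rbind, lapply(pangenomes, function(p) {
    fam <- p$families
    n <- vapply(fam$member_genomes, length, integer(1))
    data.frame(species_taxid = rep(p$species_taxid, sum(n)),
               genome_id = unlist(fam$member_genomes, use.names = FALSE),
               family90 = rep(fam$family90, n),
               family50 = rep(fam$family50, n),
               stringsAsFactors = FALSE)
  }))
}

#' Per-family pangenome statistics
#'
#' For each (species, family) pair, computes:
#' * `coreness` — fraction of the species' genomes carrying the family;
#' * `uniqueness90`/`uniqueness50` — number of *other* species whose
#'   pangenome contains the same family at the 90%/50% clustering tier;
#' * `uniqueness_sp90`/`uniqueness_sp50` — as above, excluding species
#'   flagged low quality (see [flag_low_quality_species()]);
#' * `external_genomes90`/`external_genomes50` — number of other-species
#'   *genomes* containing the family.
#'
#' @param pangenomes list of [build_pangenome()] results (>= 1 species).
#' @param low_quality named logical vector, names = species taxids (as
#'   character), covering all species; defaults to none flagged.
#' @return data.frame keyed by (`species_taxid`, `family90`).
#' @export
compute_family_stats <- function(pangenomes, low_quality = NULL) {
  stopifnot(length(pangenomes) >= 1L)
  taxids <- vapply(pangenomes, function(p) p$species_taxid, integer(1))
  if (anyDuplicated(taxids)) stop("duplicated species in pangenome list")
  names(pangenomes) <- as.character(taxids)
  if (is.null(low_quality))
    low_quality <- setNames(rep(FALSE, length(taxids)), as.character(taxids))
  if (any(!as.character(taxids) %in% names(low_quality)))
    stop("low_quality flags must cover all species")

  occ <- family_occurrences(pangenomes)
  occ$lq <- low_quality[as.character(occ$species_taxid)]

  # species- and genome-level presence tables at both tiers
  sp90 <- unique(occ[c("species_taxid", "family90", "lq")])
  sp50 <- unique(occ[c("species_taxid", "family50", "lq")])
  g90 <- unique(occ[c("species_taxid", "genome_id", "family90")])
  g50 <- unique(occ[c("species_taxid", "genome_id", "family50")])

  n_sp90 <- table(sp90$family90)
  n_sp90_hq <- table(sp90$family90[!sp90$lq])
  n_sp50 <- table(sp50$family50)
  n_sp50_hq <- table(sp50$family50[!sp50$lq])
  n_g90 <- table(g90$family90)
  n_g50 <- table(g50$family50)
  cnt <- function(tab, key) {
    v <- as.integer(tab[key]); v[is.na(v)] <- 0L; v
  }

  do.call(rbind, lapply(pangenomes, function(p) {
    fam <- p$families
    key <- as.character(p$species_taxid)
    own_lq <- low_quality[[key]]
    # presence counts of this species' own genomes, per family, by tier
    own_g90 <- fam$n_member_genomes
    own50 <- table(unique(occ[occ$species_taxid == p$species_taxid,
                              c("genome_id", "family50")])$family50)
    data.frame(
      species_taxid = p$species_taxid,
      family90 = fam$family90,
      family50 = fam$family50,
      coreness = fam$n_member_genomes / p$n_genomes,
      uniqueness90 = cnt(n_sp90, fam$family90) - 1L,
      uniqueness50 = cnt(n_sp50, fam$family50) - 1L,
      uniqueness_sp90 = cnt(n_sp90_hq, fam$family90) - (!own_lq),
      uniqueness_sp50 = cnt(n_sp50_hq, fam$family50) - (!own_lq),
      external_genomes90 = cnt(n_g90, fam$family90) - own_g90,
      external_genomes50 = cnt(n_g50, fam$family50) - cnt(own50, fam$family50),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Map each family to the other species sharing it
#'
#' @param pangenomes list of pangenomes.
#' @return data.frame (`species_taxid`, `family90`) with a list column
#'   `ext_species` of other species taxids whose pangenome contains the
#'   family at the 90% tier.
#' @export
external_species_map <- function(pangenomes) {
  occ <- unique(family_occurrences(pangenomes)[c("species_taxid", "family90")])
  by_fam <- split(occ$species_taxid, occ$family90)
  out <- occ
  out$ext_species <- Map(function(f, s) setdiff(by_fam[[f]], s),
                         occ$family90, occ$species_taxid)
  out
}

# Tier threshold table.  Boundary semantics (one place, used everywhere):
#   tier A: coreness > 0.80 (strict); uniqueness90/50 <= 2;
#           external_genomes90 <= 10; external_genomes50 <= 5
#   tier B: 0.70 < coreness <= 0.80; uniqueness90/50 <= 5;
#           external_genomes90 < 15; external_genomes50 < 10 (strict)
#   tier C: 0.50 < coreness <= 0.70; uniqueness90 < 10; uniqueness50 < 15;
#           external_genomes90 < 25; external_genomes50 < 20 (strict)
#   tier U: single-genome species with uniqueness90 = uniqueness50 = 0
tier_satisfied <- function(stats, tier) {
  with(stats, switch(
    tier,
    A = coreness > 0.80 & uniqueness90 <= 2 & uniqueness50 <= 2 &
      external_genomes90 <= 10 & external_genomes50 <= 5,
    B = coreness > 0.70 & coreness <= 0.80 &
      uniqueness90 <= 5 & uniqueness50 <= 5 &
      external_genomes90 < 15 & external_genomes50 < 10,
    C = coreness > 0.50 & coreness <= 0.70 &
      uniqueness90 < 10 & uniqueness50 < 15 &
      external_genomes90 < 25 & external_genomes50 < 20,
    U = uniqueness90 == 0 & uniqueness50 == 0,
    stop("unknown tier: ", tier)))
}

#' Assign a marker candidate tier
#'
#' Candidate marker families are binned into tiers by coreness band and
#' by how widely they are shared with other species.  Multi-genome
#' species use tiers A/B/C (mutually exclusive coreness bands); species
#' with a single genome, for which coreness is trivially 1, use tier U
#' instead, which requires the family to be shared with no other species.
#'
#' @param stats one row (or vectorized rows) of [compute_family_stats()].
#' @param n_species_genomes number of genomes of the candidate's species.
#' @return character vector over `"A"`,`"B"`,`"C"`,`"U"`, `NA` when no
#'   tier's thresholds are met.
#' @export
assign_tier <- function(stats, n_species_genomes) {
  stopifnot(length(n_species_genomes) == 1L, n_species_genomes >= 1L)
  n <- nrow(stats)
  out <- rep(NA_character_, n)
  if (n_species_genomes == 1L) {
    out[tier_satisfied(stats, "U")] <- "U"
  } else {
    for (tier in c("A", "B", "C"))
      out[is.na(out) & tier_satisfied(stats, tier)] <- tier
  }
  out
}

#' Marker candidate score
#'
#' Candidates within a tier are ranked by
#' `score = S_coreness * S_u50 * S_u90`, preferring families that are
#' highly conserved within the species (high coreness) and shared with as
#' few other species as possible (low uniqueness).  `S_coreness` is the
#' coreness fraction; each uniqueness factor is a log-shaped decay
#' `S_u(u) = -log(1 - (1e4 - min(1e4, u))/1e4 + 1e-4) * 15`, clamped at
#' zero, maximal at `u = 0` and vanishing as `u` approaches `1e4`.  The
#' `1e-4` term guards the logarithm at `u = 0`.
#'
#' @param stats rows of [compute_family_stats()] (needs `coreness`,
#'   `uniqueness90`, `uniqueness50`).
#' @return non-negative numeric vector.
#' @export
score_marker <- function(stats) {
  cor <- stats$coreness
  u90 <- stats$uniqueness90
  u50 <- stats$uniqueness50
  if (any(cor < 0 | cor > 1)) stop("coreness outside [0,1]")
  if (any(u90 < 0) || any(u50 < 0)) stop("negative uniqueness")
  s_u <- function(u) {
    v <- -log(1 - (1e4 - pmin(1e4, u)) / 1e4 + 1e-4) * 15
    pmax(v, 0)
  }
  cor * s_u(u50) * s_u(u90)
}

#' Select tiered markers for one species
#'
#' Iterative tier rounds A then B then C (a single-genome species runs
#' one U round instead).  Each round gathers the not-yet-selected
#' candidate families meeting that tier's thresholds; if a round yields
#' more than `stop_at` candidates the round's list is ranked by score and
#' markers are taken up to the overall cap, after which selection stops;
#' otherwise the round's candidates are all accumulated and the next tier
#' is tried.  A species ending with fewer than `min_markers` markers is
#' dropped (zero-row result flagged via the `"dropped"` attribute).
#' Candidates are restricted to protein lengths of 150-1500 amino acids.
#'
#' @param pangenome a [build_pangenome()] result.
#' @param stats rows of [compute_family_stats()] for this species.
#' @param ext_species optional named list `family90 -> other taxids`
#'   (see [external_species_map()]); markers with a non-empty list are
#'   quasi-markers.
#' @param max_markers overall cap per species (default 150).
#' @param min_markers retention floor per species (default 10).
#' @param stop_at round-level candidate count above which selection stops
#'   after that round (default 50).
#' @param min_protein_len,max_protein_len candidate length bounds (aa).
#' @return data.frame of markers (`marker_id`, `species_taxid`, `seq`,
#'   `length`, `tier`, `score`, `ext_species` list column, `is_unique`);
#'   zero rows with `attr(,"dropped") = TRUE` when the species fails the
#'   floor.
#' @export
select_markers <- function(pangenome, stats, ext_species = NULL,
                           max_markers = 150L, min_markers = 10L,
                           stop_at = 50L,
                           min_protein_len = 150L, max_protein_len = 1500L) {
  stopifnot(inherits(pangenome, "pangenome"))
  stats <- stats[stats$species_taxid == pangenome$species_taxid, ,
                 drop = FALSE]
  fam <- pangenome$families
  stats <- stats[match(fam$family90, stats$family90), , drop = FALSE]
  if (any(is.na(stats$family90))) stop("stats missing pangenome families")

  eligible <- fam$rep_protein_len >= min_protein_len &
    fam$rep_protein_len <= max_protein_len
  score <- score_marker(stats)

  rounds <- if (pangenome$n_genomes == 1L) "U" else c("A", "B", "C")
  selected <- integer(0)
  sel_tier <- character(0)
  for (tier in rounds) {
    cand <- which(eligible & tier_satisfied(stats, tier))
    cand <- setdiff(cand, selected)
    if (length(cand) > stop_at) {
      o <- order_score_desc_id(score[cand], fam$family90[cand])
      take <- head(cand[o], max_markers - length(selected))
      selected <- c(selected, take)
      sel_tier <- c(sel_tier, rep(tier, length(take)))
      break
    }
    selected <- c(selected, cand)
    sel_tier <- c(sel_tier, rep(tier, length(cand)))
  }

  make_result <- function(idx, tiers) {
    ext <- if (is.null(ext_species)) {
      rep(list(integer(0)), length(idx))
    } else {
      lapply(fam$family90[idx], function(f)
        as.integer(ext_species[[f]] %||% integer(0)))
    }
    out <- data.frame(
      marker_id = sprintf("%d__%s", pangenome$species_taxid,
                          fam$family90[idx]),
      species_taxid = rep(pangenome$species_taxid, length(idx)),
      family90 = fam$family90[idx],
      seq = fam$rep_seq[idx],
      length = fam$rep_len[idx],
      tier = tiers,
      score = score[idx],
      row.names = NULL, stringsAsFactors = FALSE)
    out$ext_species <- ext
    out$is_unique <- lengths(ext) == 0L
    out
  }

  if (length(selected) < min_markers) {
    res <- make_result(integer(0), character(0))
    attr(res, "dropped") <- TRUE
    attr(res, "reason") <- sprintf(
      "species %d: %d marker(s) after all tier rounds (< %d)",
      pangenome$species_taxid, length(selected), min_markers)
    return(res)
  }
  res <- make_result(selected, sel_tier)
  attr(res, "dropped") <- FALSE
  res
}

#' Refine a marker's external-species list by chunk search
#'
#' The marker sequence is split into non-overlapping 150 bp chunks and
#' each chunk is searched, on both strands, against the genomes of all
#' other species.  A species is added to the marker's external list when
#' at least 150 consecutive nucleotides of the marker occur verbatim in
#' one of its genomes.  Exact substring search stands in for a sensitive
#' read mapper and is adequate for synthetic genomes; precomputed
#' per-chunk hit lists from an external mapper can be supplied instead
#' via `chunk_hits`.
#'
#' @param marker one marker row (from [select_markers()]).
#' @param all_genomes list of [genome_record()] objects to search.
#' @param chunk_size chunk length (default 150 nt).
#' @param chunk_hits optional list (one element per chunk) of genome ids
#'   hit by that chunk, bypassing the built-in search.
#' @return the marker row with `ext_species` and `is_unique` updated.
#' @export
refine_marker_externality <- function(marker, all_genomes, chunk_size = 150L,
                                      chunk_hits = NULL) {
  stopifnot(nrow(marker) == 1L)
  if (marker$length < chunk_size)
    stop("marker shorter than ", chunk_size, " nt")
  n_chunks <- marker$length %/% chunk_size
  chunks <- substring(marker$seq,
                      (seq_len(n_chunks) - 1L) * chunk_size + 1L,
                      seq_len(n_chunks) * chunk_size)

  if (is.null(chunk_hits)) {
    foreign <- Filter(function(g) g$species_taxid != marker$species_taxid,
                      all_genomes)
    hit_sp <- integer(0)
    for (g in foreign) {
      for (ch in chunks) {
        found <- any(vapply(g$contigs, function(ctg)
          grepl(ch, ctg, fixed = TRUE) ||
            grepl(revcomp(ch), ctg, fixed = TRUE), logical(1)))
        if (found) { hit_sp <- c(hit_sp, g$species_taxid); break }
      }
    }
  } else {
    gid2sp <- setNames(
      vapply(all_genomes, function(g) g$species_taxid, integer(1)),
      vapply(all_genomes, function(g) g$genome_id, character(1)))
    hit_sp <- gid2sp[unlist(chunk_hits, use.names = FALSE)]
    hit_sp <- hit_sp[!is.na(hit_sp) & hit_sp != marker$species_taxid]
  }
  marker$ext_species[[1L]] <- sort(unique(c(marker$ext_species[[1L]],
                                            as.integer(hit_sp))))
  marker$is_unique <- length(marker$ext_species[[1L]]) == 0L
  marker
}

#' Build a complete marker database
#'
#' End-to-end database construction: genomes are grouped by species,
#' pangenomes and family statistics are computed (species with
#' low-quality names are flagged for the `uniqueness_sp` variants),
#' tiered markers are selected per species, and optionally the external
#' species lists are refined by 150 bp chunk search against all genomes.
#'
#' @param genomes list of [genome_record()] objects, any mix of species.
#' @param taxonomy taxonomy table (see [simulate_taxonomy()]): columns
#'   `taxid`, `parent_taxid`, `rank`, `name`, `avg_genome_length`.
#' @param refine logical, run [refine_marker_externality()] on every
#'   selected marker (default FALSE; quadratic in fixture size).
#' @param ... passed to [select_markers()].
#' @return object of class `marker_db`: `markers` (with
#'   `taxonomy_path`/`taxid_path`), `taxonomy`, `species` summary table,
#'   `dropped` (reasons per dropped species), `params`.
#' @export
build_marker_database <- function(genomes, taxonomy, refine = FALSE, ...) {
  taxids <- vapply(genomes, function(g) g$species_taxid, integer(1))
  by_sp <- split(genomes, taxids)
  pangenomes <- lapply(by_sp, build_pangenome)

  sp_names <- setNames(taxonomy$name, as.character(taxonomy$taxid))
  lq <- setNames(flag_low_quality_species(
    sp_names[names(pangenomes)]), names(pangenomes))
  stats <- compute_family_stats(pangenomes, lq)
  ext_df <- external_species_map(pangenomes)

  markers <- list()
  dropped <- character(0)
  for (p in pangenomes) {
    key <- ext_df$species_taxid == p$species_taxid
    ext <- setNames(ext_df$ext_species[key], ext_df$family90[key])
    m <- select_markers(p, stats, ext_species = ext, ...)
    if (isTRUE(attr(m, "dropped"))) {
      dropped <- c(dropped, attr(m, "reason"))
    } else if (nrow(m)) {
      markers[[as.character(p$species_taxid)]] <- m
    }
  }
  markers <- if (length(markers)) {
    do.call(rbind, c(markers, list(make.row.names = FALSE)))
  } else {
    select_markers(pangenomes[[1L]], stats,
                   max_markers = 0L, min_markers = 0L)[0L, ]
  }

  if (refine && nrow(markers)) {
    for (i in seq_len(nrow(markers)))
      markers[i, ] <- refine_marker_externality(markers[i, ], genomes)
  }

  if (nrow(markers)) {
    paths <- taxonomy_paths(taxonomy)
    idx <- match(markers$species_taxid, paths$taxid)
    markers$taxonomy_path <- paths$taxonomy_path[idx]
    markers$taxid_path <- paths$taxid_path[idx]
  } else {
    markers$taxonomy_path <- character(0)
    markers$taxid_path <- character(0)
  }

  kept <- unique(markers$species_taxid)
  species <- data.frame(
    species_taxid = vapply(pangenomes, function(p) p$species_taxid,
                           integer(1)),
    n_genomes = vapply(pangenomes, function(p) p$n_genomes, integer(1)),
    low_quality = as.logical(lq),
    row.names = NULL, stringsAsFactors = FALSE)
  species$n_markers <- vapply(species$species_taxid, function(t)
    sum(markers$species_taxid == t), integer(1))
  species$retained <- species$species_taxid %in% kept

  structure(list(markers = markers, taxonomy = taxonomy,
                 species = species, stats = stats, dropped = dropped,
                 params = list(...)),
            class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf(
    "<marker_db  %d marker(s), %d/%d species retained, tiers: %s>\n",
    nrow(x$markers), sum(x$species$retained), nrow(x$species),
    paste(names(table(x$markers$tier)), table(x$markers$tier),
          sep = ":", collapse = " ")))
  invisible(x)
}
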