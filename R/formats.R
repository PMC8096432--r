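# Readers and writers for the interchange formats: the tab-separated
# profile dialect with rank-prefixed clade paths, the CAMI profiling
# format, presence/absence matrices, marker databases (FASTA +
# metadata), gene tables, FASTQ and tabular alignment records.

fmt_num <- function(x) trimws(formatC(x, digits = 15, format = "g"))

#' Serialize a taxonomic profile
#'
#' Two dialects are supported.  The default (`"metaphlan"`) writes
#' comment headers followed by
#' `clade_path<TAB>taxid_path<TAB>relative_abundance` rows, with the
#' unknown fraction as a leading `UNKNOWN` row.  `"cami"` writes the
#' CAMI profiling format (`@SampleID`/`@Version`/`@Ranks` headers and
#' `TAXID RANK TAXPATH TAXPATHSN PERCENTAGE` rows).
#'
#' @param profile a `tax_profile` (see [profile_taxa()]).
#' @param format `"metaphlan"` or `"cami"`.
#' @param sample_id sample name in the headers.
#' @param file optional path; when given, lines are written there.
#' @return the text lines, invisibly when `file` is given.
#' @export
write_profile <- function(profile, format = c("metaphlan", "cami"),
                          sample_id = "sample", file = NULL) {
  format <- match.arg(format)
  unknown <- attr(profile, "unknown_fraction") %||% 0
  if (format == "metaphlan") {
    lines <- c(
      paste0("#SampleID\t", sample_id),
      "#clade_name\tNCBI_tax_id\trelative_abundance",
      paste("UNKNOWN", "-1", fmt_num(unknown), sep = "\t"),
      if (nrow(profile))
        paste(profile$taxonomy_path, profile$taxid_path,
              fmt_num(profile$relative_abundance), sep = "\t"))
  } else {
    lines <- c(
      paste0("@SampleID:", sample_id),
      "@Version:0.9.1",
      paste0("@Ranks:", paste(RANK_ORDER, collapse = "|")),
      "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
      if (nrow(profile))
        paste(profile$taxid, profile$rank, profile$taxid_path,
              gsub("[kpcofgs]__", "", profile$taxonomy_path),
              fmt_num(profile$relative_abundance), sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a taxonomic profile
#'
#' Inverse of [write_profile()]; `read_profile(write_profile(p, f), f)`
#' reproduces the clade table of `p` (and, for the `"metaphlan"`
#' dialect, its unknown fraction).
#'
#' @param lines character vector of lines, or a file path.
#' @param format `"metaphlan"` or `"cami"`.
#' @return a `tax_profile` data.frame.
#' @export
read_profile <- function(lines, format = c("metaphlan", "cami")) {
  format <- match.arg(format)
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  unknown <- 0
  if (format == "metaphlan") {
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    is_unknown <- vapply(parts, function(p) p[[1L]] == "UNKNOWN",
                         logical(1))
    if (any(is_unknown))
      unknown <- as.numeric(parts[[which(is_unknown)[1L]]][[3L]])
    parts <- parts[!is_unknown]
    tax_path <- vapply(parts, `[[`, character(1), 1L)
    tid_path <- vapply(parts, `[[`, character(1), 2L)
    ab <- as.numeric(vapply(parts, `[[`, character(1), 3L))
    depth <- lengths(strsplit(tax_path, "|", fixed = TRUE))
    taxid <- as.integer(vapply(strsplit(tid_path, "|", fixed = TRUE),
                               function(p) p[[length(p)]], character(1)))
    rank <- RANK_ORDER[depth]
  } else {
    body <- lines[!startsWith(lines, "@") & nzchar(lines)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    taxid <- as.integer(vapply(parts, `[[`, character(1), 1L))
    rank <- vapply(parts, `[[`, character(1), 2L)
    tid_path <- vapply(parts, `[[`, character(1), 3L)
    names_path <- strsplit(vapply(parts, `[[`, character(1), 4L), "|",
                           fixed = TRUE)
    tax_path <- vapply(names_path, function(nm)
      paste0(RANK_PREFIX[RANK_ORDER[seq_along(nm)]], nm,
             collapse = "|"), character(1))
    ab <- as.numeric(vapply(parts, `[[`, character(1), 5L))
  }
  out <- data.frame(taxid = taxid, rank = rank, taxonomy_path = tax_path,
                    taxid_path = tid_path, relative_abundance = ab,
                    stringsAsFactors = FALSE)
  structure(out, class = c("tax_profile", "data.frame"),
            unknown_fraction = unknown, total_reads = NA_integer_,
            species_coverage = numeric(0))
}

#' Write / read a presence/absence matrix
#'
#' Tab-separated, families as rows (first column `family`), samples as
#' columns; entries 0/1.
#'
#' @param m binary integer matrix with dimnames.
#' @param file path.
#' @return `read_presence_absence` returns the integer matrix.
#' @export
write_presence_absence <- function(m, file) {
  df <- data.frame(family = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_presence_absence
#' @export
read_presence_absence <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$family
  m
}

#' Write a marker database to a directory
#'
#' Produces `markers.fasta` (headers `marker_id species_taxid tier`),
#' `markers.tsv` (metadata incl. comma-joined external species),
#' `taxonomy.tsv` and a `manifest.json` with build parameters and
#' content hashes.
#'
#' @param db a `marker_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_marker_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- db$markers
  seqs <- Biostrings::DNAStringSet(setNames(
    m$seq, sprintf("%s %d %s", m$marker_id, m$species_taxid, m$tier)))
  Biostrings::writeXStringSet(seqs, file.path(dir, "markers.fasta"))

  meta <- data.frame(
    marker_id = m$marker_id, species_taxid = m$species_taxid,
    family90 = m$family90, tier = m$tier, score = m$score,
    length = m$length,
    ext_species = vapply(m$ext_species, paste, character(1),
                         collapse = ","),
    taxonomy_path = m$taxonomy_path, taxid_path = m$taxid_path,
    stringsAsFactors = FALSE)
  write.table(meta, file.path(dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(db$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    n_markers = nrow(m),
    n_species = length(unique(m$species_taxid)),
    params = db$params,
    hashes = as.list(tools::md5sum(file.path(
      dir, c("markers.fasta", "markers.tsv", "taxonomy.tsv")))))
  names(manifest$hashes) <- basename(names(manifest$hashes))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a marker database directory
#'
#' @param dir directory written by [write_marker_db()].
#' @return a `marker_db` object (without per-family statistics).
#' @export
read_marker_db <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "markers.fasta"))
  ids <- vapply(strsplit(names(seqs), " ", fixed = TRUE), `[[`,
                character(1), 1L)
  meta <- read.delim(file.path(dir, "markers.tsv"),
                     stringsAsFactors = FALSE)
  taxonomy <- read.delim(file.path(dir, "taxonomy.tsv"),
                         stringsAsFactors = FALSE)
  meta$seq <- as.character(seqs)[match(meta$marker_id, ids)]
  meta$ext_species <- lapply(strsplit(
    ifelse(is.na(meta$ext_species), "", meta$ext_species), ","),
    function(x) as.integer(x[nzchar(x)]))
  meta$is_unique <- lengths(meta$ext_species) == 0L
  structure(list(markers = meta, taxonomy = taxonomy,
                 species = NULL, stats = NULL, dropped = character(0),
                 params = list()),
            class = "marker_db")
}

#' Write / read simulated reads as FASTQ (Phred+33)
#'
#' @param reads read data.frame from [simulate_reads()].
#' @param file path.
#' @return `read_fastq` returns a data.frame `read_id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, file) {
  lines <- character(4L * nrow(reads))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(file) {
  lines <- readLines(file)
  stopifnot(length(lines) %% 4L == 0L)
  data.frame(read_id = sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)]),
             seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
             qual = lines[c(FALSE, FALSE, FALSE, TRUE)],
             stringsAsFactors = FALSE)
}

#' Write / read tabular alignment records
#'
#' The tab-separated alignment interchange used in place of SAM for
#' text-only workflows; columns mirror [truth_alignments()].
#'
#' @param alignments alignment data.frame.
#' @param file path.
#' @return `read_alignments` returns the data.frame.
#' @export
write_alignments <- function(alignments, file) {
  write.table(alignments, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Write / read annotated genomes as FASTA plus a gene table
#'
#' Contig headers are `genome_id|contig_id`; the tab-separated gene
#' table carries `gene_id`, `genome_id`, `contig`, `start`, `end`
#' (0-based half-open), `strand`, `family90`, `family50`, `protein_len`
#' and `species_taxid`.
#'
#' @param genomes list of [genome_record()] objects.
#' @param fasta,genes_tsv output paths.
#' @return `read_genomes` returns the list of genome records (named by
#'   genome id).
#' @export
write_genomes <- function(genomes, fasta, genes_tsv) {
  seqs <- do.call(c, unname(lapply(genomes, function(g)
    setNames(unname(g$contigs),
             paste(g$genome_id, names(g$contigs), sep = "|")))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  tab <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g$genes)) return(NULL)
    cbind(g$genes[c("gene_id", "contig", "start", "end", "strand",
                    "family90", "family50", "protein_len")],
          genome_id = g$genome_id, species_taxid = g$species_taxid)
  }))
  write.table(tab, genes_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta)
}

#' @rdname write_genomes
#' @export
read_genomes <- function(fasta, genes_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gid <- vapply(parts, `[[`, character(1), 1L)
  cid <- vapply(parts, function(p) paste(p[-1L], collapse = "|"),
                character(1))
  genes <- read.delim(genes_tsv, stringsAsFactors = FALSE)
  out <- lapply(unique(gid), function(g) {
    contigs <- setNames(as.character(seqs[gid == g]), cid[gid == g])
    gg <- genes[genes$genome_id == g, , drop = FALSE]
    genome_record(g, unique(gg$species_taxid)[1L], contigs,
                  gg[c("gene_id", "contig", "start", "end", "strand",
                       "protein_len", "family90", "family50")])
  })
  names(out) <- unique(gid)
  out
}

#' Write / read a distance matrix
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param file path.
#' @return `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(d, file) {
  df <- data.frame(sample = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample
  m
}
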