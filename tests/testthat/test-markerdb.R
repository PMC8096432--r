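# Pangenome construction, family statistics, tier assignment, scoring
# and marker selection.

test_that("low-quality species names are flagged case-sensitively", {
  expect_true(flag_low_quality_species("Candidatus_Foo_bar"))
  expect_true(flag_low_quality_species("candidate_division_WS6"))
  expect_true(flag_low_quality_species("Clostridium_sp_ABC"))
  expect_true(flag_low_quality_species("Clostridium_sp"))
  expect_true(flag_low_quality_species("marine_bacterium_X"))
  expect_true(flag_low_quality_species("uncultured_archaeon_Y"))
  expect_true(flag_low_quality_species("unidentified_organism"))
  expect_false(flag_low_quality_species("Ruminococcus_bromii"))
  expect_false(flag_low_quality_species("Clostridium_spiroforme"))
  expect_false(flag_low_quality_species("Mycobacterium_tuberculosis"))
  expect_false(flag_low_quality_species(""))
  expect_equal(flag_low_quality_species(c("A_sp_1", "B_b")), c(TRUE, FALSE))
})

test_that("pangenome is the union of family sets with full membership", {
  # genomes with family sets {a,b,c} and {b,c,d}
  memb <- cbind(c(TRUE, TRUE, TRUE, FALSE), c(FALSE, TRUE, TRUE, TRUE))
  gs <- make_species_genomes(101L, memb, fam90 = c("a", "b", "c", "d"),
                             seed = 3L)
  p <- build_pangenome(gs)
  expect_setequal(p$families$family90, c("a", "b", "c", "d"))
  expect_equal(p$families["b", "n_member_genomes"], 2L)
  expect_equal(sort(p$families$member_genomes[["c"]]), p$genome_ids)
  # representative is from the lexicographically smallest genome id
  expect_equal(unique(p$families$rep_genome[p$families$family90
                                            %in% c("b", "c")]), "G101_01")
  expect_equal(p$families["d", "rep_genome"], "G101_02")
})

test_that("pangenome rejects empty and mixed-species input", {
  expect_error(build_pangenome(list()), "no genomes")
  gs1 <- make_species_genomes(101L, matrix(TRUE, 2, 1), seed = 4L)
  gs2 <- make_species_genomes(102L, matrix(TRUE, 2, 1), seed = 5L)
  expect_error(build_pangenome(c(gs1, gs2)), "mixed species")
})

test_that("family statistics agree with a brute-force double loop", {
  u <- simulate_universe(6, genomes_per_species = c(3, 4, 2, 1, 3, 5),
                         n_core = 6, n_accessory = 6, n_shared = 3,
                         seed = 11)
  taxids <- vapply(u$genomes, function(g) g$species_taxid, integer(1))
  pans <- lapply(split(u$genomes, taxids), build_pangenome)
  lq <- setNames(c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
                 names(pans))
  stats <- compute_family_stats(pans, lq)

  # brute force over (species x genomes x families)
  fam_of_genome <- lapply(u$genomes, function(g)
    list(f90 = unique(g$genes$family90), f50 = unique(g$genes$family50),
         sp = g$species_taxid))
  for (i in sample.int(nrow(stats), 40)) {
    s <- stats$species_taxid[i]; f90 <- stats$family90[i]
    f50 <- stats$family50[i]
    own <- Filter(function(x) x$sp == s, fam_of_genome)
    other <- Filter(function(x) x$sp != s, fam_of_genome)
    expect_equal(stats$coreness[i],
                 mean(vapply(own, function(x) f90 %in% x$f90, logical(1))))
    sp90 <- unique(vapply(Filter(function(x) f90 %in% x$f90, other),
                          function(x) x$sp, integer(1)))
    sp50 <- unique(vapply(Filter(function(x) f50 %in% x$f50, other),
                          function(x) x$sp, integer(1)))
    expect_equal(stats$uniqueness90[i], length(sp90))
    expect_equal(stats$uniqueness50[i], length(sp50))
    expect_equal(stats$uniqueness_sp90[i],
                 sum(!lq[as.character(sp90)]))
    expect_equal(stats$uniqueness_sp50[i],
                 sum(!lq[as.character(sp50)]))
    expect_equal(stats$external_genomes90[i],
                 sum(vapply(other, function(x) f90 %in% x$f90, logical(1))))
    expect_equal(stats$external_genomes50[i],
                 sum(vapply(other, function(x) f50 %in% x$f50, logical(1))))
    expect_lte(stats$uniqueness_sp90[i], stats$uniqueness90[i])
    expect_gte(stats$external_genomes90[i], stats$uniqueness90[i])
  }
})

make_stats <- function(coreness, u90 = 0L, u50 = 0L, eg90 = 0L, eg50 = 0L) {
  data.frame(coreness = coreness, uniqueness90 = u90, uniqueness50 = u50,
             external_genomes90 = eg90, external_genomes50 = eg50)
}

test_that("tier thresholds follow the printed boundary semantics", {
  expect_equal(assign_tier(make_stats(0.85, 1, 1, 5, 2), 10), "A")
  expect_equal(assign_tier(make_stats(0.75, 5, 5, 14, 9), 10), "B")
  expect_equal(assign_tier(make_stats(0.60, 9, 14, 24, 19), 10), "C")
  expect_equal(assign_tier(make_stats(1.0, 0, 0, 0, 0), 1), "U")
  # boundaries: coreness 0.80 is tier B, not A; eg90 = 15 fails B
  expect_equal(assign_tier(make_stats(0.80, 2, 2, 5, 2), 10), "B")
  expect_equal(assign_tier(make_stats(0.75, 5, 5, 15, 9), 10),
               NA_character_)
  expect_equal(assign_tier(make_stats(0.50, 0, 0, 0, 0), 10),
               NA_character_)
  # single-genome species with any sharing gets no tier
  expect_equal(assign_tier(make_stats(1.0, 1, 0, 1, 0), 1), NA_character_)
})

test_that("tier coreness bands are mutually exclusive", {
  grid <- expand.grid(coreness = seq(0.50, 1.00, by = 0.01),
                      u = c(0L, 2L, 5L, 9L), eg = c(0L, 5L, 14L, 24L))
  for (i in seq_len(nrow(grid))) {
    s <- make_stats(grid$coreness[i], grid$u[i], grid$u[i],
                    grid$eg[i], grid$eg[i])
    sat <- vapply(c("A", "B", "C"),
                  function(t) metamark:::tier_satisfied(s, t), logical(1))
    expect_lte(sum(sat), 1L)
  }
})

test_that("marker score matches the regularized formula and its shape", {
  s_u0 <- -log(1e-4) * 15
  expect_equal(score_marker(make_stats(1, 0, 0)), s_u0^2, tolerance = 1e-9)
  expect_equal(score_marker(make_stats(1, 0, 0)), 19086.8, tolerance = 1e-4)
  expect_equal(score_marker(make_stats(1, 1e4, 1e4)), 0) # clamped
  expect_equal(score_marker(make_stats(0.5, 0, 0)), 0.5 * s_u0^2,
               tolerance = 1e-9)
  expect_error(score_marker(make_stats(1, -1, 0)), "negative")
  expect_error(score_marker(make_stats(1.2, 0, 0)), "coreness")

  # strictly decreasing in each uniqueness count below 1e4
  u_grid <- c(0, 1, 5, 50, 500, 5000, 9999)
  sc90 <- score_marker(make_stats(0.9, u_grid, 0))
  sc50 <- score_marker(make_stats(0.9, 0, u_grid))
  expect_true(all(diff(sc90) < 0))
  expect_true(all(diff(sc50) < 0))
  # weakly increasing in coreness
  sc_c <- score_marker(make_stats(seq(0, 1, 0.1), 3, 3))
  expect_true(all(diff(sc_c) >= 0))
})

test_that("marker selection caps, accumulates across tiers and drops", {
  # 200 tier-A candidates -> exactly the 150 highest-scoring, all tier A
  memb <- matrix(TRUE, 200, 2)
  gs <- make_species_genomes(201L, memb, seed = 21L)
  p <- build_pangenome(gs)
  st <- compute_family_stats(list(p))
  m <- select_markers(p, st)
  expect_equal(nrow(m), 150L)
  expect_true(all(m$tier == "A"))
  sc <- score_marker(st)
  expect_equal(sort(m$score), sort(sc)[(200 - 150 + 1):200])

  # 30 tier-A + 40 tier-B candidates -> 70 markers over both tiers
  memb <- rbind(matrix(TRUE, 30, 4),
                matrix(rep(c(TRUE, TRUE, TRUE, FALSE), each = 40), 40, 4))
  gs <- make_species_genomes(202L, memb, seed = 22L)
  p <- build_pangenome(gs)
  st <- compute_family_stats(list(p))
  m <- select_markers(p, st)
  expect_equal(nrow(m), 70L)
  expect_equal(as.vector(table(m$tier)[c("A", "B")]), c(30L, 40L))

  # 4 candidates after tier C -> species dropped
  gs <- make_species_genomes(203L, matrix(TRUE, 4, 2), seed = 23L)
  p <- build_pangenome(gs)
  m <- select_markers(p, compute_family_stats(list(p)))
  expect_equal(nrow(m), 0L)
  expect_true(attr(m, "dropped"))
})

test_that("marker selection respects candidate protein-length bounds", {
  seqs <- c(random_gene_seqs(5, len = 450L, seed = 31L),
            random_gene_seqs(5, len = 444L, seed = 32L),  # 148 aa
            random_gene_seqs(5, len = 4503L, seed = 33L)) # 1501 aa
  gs <- make_species_genomes(204L, matrix(TRUE, 15, 2), seqs = seqs,
                             seed = 34L)
  p <- build_pangenome(gs)
  m <- select_markers(p, compute_family_stats(list(p)), min_markers = 5L)
  expect_equal(nrow(m), 5L)
  expect_true(all(m$length == 450L))
})

test_that("selected tier labels match an independent reassignment", {
  for (seed in c(41L, 42L)) {
    u <- simulate_universe(5, genomes_per_species = c(4, 3, 1, 5, 4),
                           n_core = 8, n_accessory = 10, n_shared = 2,
                           seed = seed)
    taxids <- vapply(u$genomes, function(g) g$species_taxid, integer(1))
    pans <- lapply(split(u$genomes, taxids), build_pangenome)
    stats <- compute_family_stats(pans)
    for (p in pans) {
      m <- select_markers(p, stats, min_markers = 1L)
      if (!nrow(m)) next
      expect_lte(nrow(m), 150L)
      st <- stats[stats$species_taxid == p$species_taxid, ]
      st <- st[match(m$family90, st$family90), ]
      expect_equal(m$tier, assign_tier(st, p$n_genomes))
    }
  }
})

test_that("chunk search refines external species on either strand", {
  gs <- make_species_genomes(301L, matrix(TRUE, 3, 1),
                             seqs = random_gene_seqs(3, 600L, seed = 51L),
                             seed = 52L)
  p <- build_pangenome(gs)
  st <- compute_family_stats(list(p))
  m <- select_markers(p, st, min_markers = 1L)

  # plant marker 1's first 150 bp into a foreign genome, forward strand;
  # marker 2's second chunk reverse-complemented into another
  chunk1 <- substr(m$seq[1], 1, 150)
  chunk2 <- revcomp(substr(m$seq[2], 151, 300))
  foreign1 <- genome_record("GX_01", 999L,
                            c(c1 = paste0(random_gene_seqs(1, 200, 53L),
                                          chunk1,
                                          random_gene_seqs(1, 200, 54L))),
                            data.frame(gene_id = character(0),
                                       contig = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0),
                                       protein_len = integer(0),
                                       family90 = character(0),
                                       family50 = character(0)))
  foreign2 <- genome_record("GY_01", 998L,
                            c(c1 = paste0(random_gene_seqs(1, 100, 55L),
                                          chunk2)),
                            foreign1$genes)

  r1 <- refine_marker_externality(m[1, ], list(foreign1, foreign2))
  expect_equal(r1$ext_species[[1]], 999L)
  expect_false(r1$is_unique)
  r2 <- refine_marker_externality(m[2, ], list(foreign1, foreign2))
  expect_equal(r2$ext_species[[1]], 998L)
  r3 <- refine_marker_externality(m[3, ], list(foreign1, foreign2))
  expect_equal(r3$ext_species[[1]], integer(0))
  expect_true(r3$is_unique)

  short <- m[1, ]; short$length <- 120L
  expect_error(refine_marker_externality(short, list(foreign1)),
               "shorter")
  # externally supplied per-chunk hit lists bypass the built-in search
  r4 <- refine_marker_externality(m[3, ], list(foreign1, foreign2),
                                  chunk_hits = list("GX_01", character(0)))
  expect_equal(r4$ext_species[[1]], 999L)
})

test_that("database build drops marker-poor species and fills lineages", {
  u <- simulate_universe(3, genomes_per_species = 2, n_core = 12, seed = 61)
  # make species 3 marker-poor by keeping only 4 families
  poor <- lapply(u$genomes[vapply(u$genomes, function(g)
    g$species_taxid == 10003L, logical(1))], function(g) {
      g$genes <- g$genes[1:4, ]
      g
    })
  rich <- u$genomes[vapply(u$genomes, function(g)
    g$species_taxid != 10003L, logical(1))]
  db <- build_marker_database(c(rich, poor), u$taxonomy)
  expect_setequal(unique(db$markers$species_taxid), c(10001L, 10002L))
  expect_length(db$dropped, 1L)
  expect_match(db$dropped, "10003")
  expect_true(all(grepl("^k__Bacteria\\|.*\\|s__", db$markers$taxonomy_path)))
  expect_true(all(vapply(strsplit(db$markers$taxid_path, "|", fixed = TRUE),
                         length, integer(1)) == 7L))
})
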