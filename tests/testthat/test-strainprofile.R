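# Consensus calling, sample/marker filtering, concatenation, K2P
# distances, NJ trees, normalized distances and transmission inference.

test_that("consensus calls majority bases under quality and dominance rules", {
  # 9 A's vs 1 G at one column, high quality -> A (dominance 0.9)
  a <- make_pileup_alignments("m", c(rep("A", 9), "G"), rep(0L, 10),
                              qual = 35L)
  pile <- build_pileup(a, 1L)
  cons <- call_consensus(pile, min_reads = 1L, min_breadth = 0)
  expect_equal(cons$seq, "A")

  # 7 vs 3 -> dominance 0.7 < 0.8 -> N
  a <- make_pileup_alignments("m", c(rep("A", 7), rep("G", 3)), rep(0L, 10))
  cons <- call_consensus(build_pileup(a, 1L), min_reads = 1L,
                         min_breadth = 0)
  expect_equal(cons$seq, "N")

  # mean column quality below 30 -> N even when unanimous
  a <- make_pileup_alignments("m", rep("A", 10), rep(0L, 10), qual = 25L)
  cons <- call_consensus(build_pileup(a, 1L), min_reads = 1L,
                         min_breadth = 0)
  expect_equal(cons$seq, "N")

  # uncovered positions are N and excluded from breadth
  a <- make_pileup_alignments("m", rep("ACGT", 8), rep(0L, 8))
  cons <- call_consensus(build_pileup(a, 10L), min_reads = 1L,
                         min_breadth = 0)
  expect_equal(cons$seq, "ACGTNNNNNN")
  expect_equal(cons$breadth, 0.4)
})

test_that("consensus markers below read or breadth floors are rejected", {
  # 75 of 100 positions covered at depth 10 -> breadth 0.75 -> rejected
  a <- make_pileup_alignments("m", rep(strrep("A", 75), 10), rep(0L, 10))
  cons <- call_consensus(build_pileup(a, 100L))
  expect_match(cons$status, "breadth 0.750")

  # 7 reads -> rejected regardless of breadth
  a <- make_pileup_alignments("m", rep(strrep("A", 100), 7), rep(0L, 7))
  cons <- call_consensus(build_pileup(a, 100L))
  expect_match(cons$status, "7 read\\(s\\) < 8")

  # 8 reads at full breadth -> accepted
  a <- make_pileup_alignments("m", rep(strrep("A", 100), 8), rep(0L, 8))
  expect_equal(call_consensus(build_pileup(a, 100L))$status, "ok")
})

test_that("sample/marker filtering reaches a consistent fixed point", {
  # sample with 19 markers is dropped
  pres <- rbind(
    expand.grid(sample_id = c("s1", "s2", "s3"),
                marker_id = sprintf("m%02d", 1:25),
                stringsAsFactors = FALSE),
    data.frame(sample_id = "s4", marker_id = sprintf("m%02d", 1:19),
               stringsAsFactors = FALSE))
  f <- filter_samples_and_markers(pres)
  expect_setequal(f$samples, c("s1", "s2", "s3"))
  expect_length(f$markers, 25L)

  # marker in 79% of samples is dropped (100 samples, 79 carry m_rare)
  pres <- rbind(
    expand.grid(sample_id = sprintf("s%03d", 1:100),
                marker_id = sprintf("m%02d", 1:20),
                stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("s%03d", 1:79), marker_id = "m_rare",
               stringsAsFactors = FALSE))
  f <- filter_samples_and_markers(pres)
  expect_false("m_rare" %in% f$markers)
  expect_length(f$samples, 100L)

  # fixed point satisfies both thresholds simultaneously
  set.seed(101)
  pres <- expand.grid(sample_id = sprintf("s%02d", 1:30),
                      marker_id = sprintf("m%02d", 1:40),
                      stringsAsFactors = FALSE)
  pres <- pres[runif(nrow(pres)) < 0.92, ]
  f <- filter_samples_and_markers(pres)
  tab_s <- table(f$presence$sample_id)
  tab_m <- table(f$presence$marker_id)
  expect_true(all(tab_s >= 20))
  expect_true(all(tab_m >= 0.8 * length(f$samples)))

  expect_error(filter_samples_and_markers(
    data.frame(sample_id = "s1", marker_id = "m1")), "insufficient data")
})

test_that("boundary trimming slices and drops as specified", {
  s300 <- strrep("A", 300)
  expect_equal(nchar(trim_consensus(s300)), 200L)
  expect_equal(trim_consensus(paste0(strrep("C", 50), "G",
                                     strrep("T", 50))), "G")
  expect_warning(out <- trim_consensus(strrep("A", 100)), "dropped")
  expect_null(out)
})

test_that("concatenation fixes marker order and N-fills missing markers", {
  cs <- list(
    sA = list(m1 = strrep("A", 150), m2 = strrep("C", 200)),
    sB = list(m2 = strrep("G", 200), m1 = strrep("T", 150)),
    sC = list(m1 = strrep("A", 150)))
  out <- concatenate_alignment(cs, trim = 50L)
  expect_equal(attr(out, "marker_order"), c("m1", "m2"))
  expect_equal(unname(nchar(out)), rep(150L, 3))  # 50 + 100 columns
  expect_equal(unname(out["sA"]), paste0(strrep("A", 50), strrep("C", 100)))
  expect_equal(unname(out["sC"]), paste0(strrep("A", 50), strrep("N", 100)))
  # identical inputs give identical rows
  expect_equal(unname(out["sB"]), paste0(strrep("T", 50), strrep("G", 100)))

  bad <- list(sA = list(m1 = strrep("A", 200)),
              sB = list(m1 = strrep("A", 210)))
  expect_error(concatenate_alignment(bad), "length mismatch")
})

test_that("Kimura distance matches closed form and a site-count oracle", {
  expect_equal(kimura2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # 100 sites, 10 transitions (A<->G), 0 transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(kimura2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  expect_true(is.na(kimura2p_distance("NNNN", "ACGT")))
  expect_error(kimura2p_distance("AC", "ACG"), "length")

  # fuzz on random 50-mers against an independent implementation (ape K80)
  set.seed(7)
  for (i in 1:25) {
    x <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    y0 <- strsplit(x, "")[[1]]
    flip <- sample(50, sample(0:8, 1))
    for (j in flip) y0[j] <- sample(setdiff(c("A", "C", "G", "T"), y0[j]), 1)
    y <- paste(y0, collapse = "")
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(list(
      a = strsplit(tolower(x), "")[[1]],
      b = strsplit(tolower(y), "")[[1]])), model = "K80"))["a", "b"]
    expect_equal(kimura2p_distance(x, y), unname(ref), tolerance = 1e-10)
  }
})

test_that("distance matrix form agrees with the scalar distance", {
  set.seed(8)
  base <- sample(c("A", "C", "G", "T"), 120, TRUE)
  seqs <- setNames(vapply(1:4, function(i) {
    x <- base
    for (j in sample(120, 8)) x[j] <- sample(c("A", "C", "G", "T", "N"), 1)
    paste(x, collapse = "")
  }, character(1)), paste0("s", 1:4))
  d <- strain_distance_matrix(seqs)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), names(seqs)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], kimura2p_distance(seqs[[i]], seqs[[j]]))
})

test_that("neighbor joining recovers 3-taxon branch lengths and additivity", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 3))

  # additive matrices are reproduced exactly (random trees, 4-6 taxa)
  set.seed(9)
  for (n in 4:6) {
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    d0 <- ape::cophenetic.phylo(tr0)
    d1 <- ape::cophenetic.phylo(nj_tree(d0))[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-8)
  }

  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d_na <- d; d_na[1, 2] <- d_na[2, 1] <- NA
  expect_error(nj_tree(d_na), "missing")
})

test_that("tree-normalized distances are path length over total length", {
  tr <- ape::read.tree(text = "(a:1,b:1,c:3);")
  nd <- normalized_tree_distances(tr)
  expect_equal(nd$distances["a", "b"], 0.4)
  expect_equal(nd$distances["a", "c"], 0.8)
  expect_equal(diag(nd$distances), c(a = 0, b = 0, c = 0))
  # scale invariance
  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  expect_equal(normalized_tree_distances(tr10)$distances, nd$distances)
  expect_true(all(nd$distances >= 0 & nd$distances <= 1))
})

test_that("transmission threshold is the capped first percentile", {
  # 15 samples; 5 related pairs at 0.5; the 100 unrelated pairs take
  # distances 1..100 -> threshold = quantile(1:100, 0.01) = 1.99
  ids <- sprintf("x%02d", 1:15)
  d <- matrix(0, 15, 15, dimnames = list(ids, ids))
  rel <- data.frame(sample_a = ids[seq(1, 9, 2)],
                    sample_b = ids[seq(2, 10, 2)])
  pool <- sample(1:100)  # assignment order is irrelevant
  k <- 0
  for (i in 1:14) for (j in (i + 1):15) {
    related <- any(rel$sample_a == ids[i] & rel$sample_b == ids[j])
    v <- if (related) 0.5 else { k <- k + 1; pool[k] }
    d[i, j] <- d[j, i] <- v
  }
  meta <- data.frame(sample_id = ids, subject_id = ids,
                     collection_date = "2020-01-01")
  tc <- infer_transmission(d, meta, rel)  # exactly 100 unrelated pairs
  expect_equal(tc$threshold, 1.99)
  expect_equal(nrow(tc$events), 5L)
  expect_true(all(tc$events$distance < tc$threshold))
  expect_lte(tc$unrelated_below_threshold, 0.01)

  # related pair above the threshold is not an event
  d2 <- d
  d2[rel$sample_a[1], rel$sample_b[1]] <-
    d2[rel$sample_b[1], rel$sample_a[1]] <- 50
  tc2 <- infer_transmission(d2, meta, rel)
  expect_equal(nrow(tc2$events), 4L)
})

test_that("longitudinal subjects contribute their earliest sample only", {
  ids <- c(sprintf("u%02d", 1:12), "dupA", "dupB")
  set.seed(10)
  d <- matrix(0, 14, 14, dimnames = list(ids, ids))
  d[upper.tri(d)] <- runif(sum(upper.tri(d)), 1, 2)
  d <- d + t(d)
  meta <- data.frame(
    sample_id = ids,
    subject_id = c(sprintf("subj%02d", 1:12), "subjX", "subjX"),
    collection_date = c(rep("2020-01-01", 12), "2020-06-01", "2020-02-01"))
  no_rel <- data.frame(sample_a = character(0), sample_b = character(0))
  expect_warning(infer_transmission(d, meta, no_rel), "unstable")
  tc <- suppressWarnings(infer_transmission(d, meta, no_rel))
  expect_equal(tc$n_unrelated_pairs, choose(13, 2))  # dupA excluded
})

test_that("polymorphic rate report counts ambiguous sites", {
  cs <- list(s1 = list(m1 = "ACGTN", m2 = "NNACG"),
             s2 = list(m1 = "ACGTA"))
  pr <- polymorphic_rates(cs)
  expect_equal(pr$rate[pr$sample_id == "s1"], 0.3)
  expect_equal(pr$rate[pr$sample_id == "s2"], 0)
})
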