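# Family coverage normalization, coverage-curve presence/absence
# calling, matrix clustering and the locus-compactness test.

test_that("family coverage is base counts over mean gene length", {
  dep <- c(g1 = 2, g2 = 2)
  len <- c(g1 = 300, g2 = 500)
  fam <- c(g1 = "f", g2 = "f")
  expect_equal(unname(family_coverage(dep, len, fam)),
               (2 * 300 + 2 * 500) / 400)
  # single-gene family: coverage equals gene depth
  expect_equal(unname(family_coverage(c(g = 3.5), c(g = 777),
                                      c(g = "f"))), 3.5)
  # genes missing from the depth vector count as zero
  expect_equal(unname(family_coverage(numeric(0), len, fam)), 0)
  expect_error(family_coverage(dep, c(g1 = 0, g2 = 500), fam), "")
})

test_that("family coverage is invariant to fragmenting alignments", {
  # one 600 nt gene covered by one 300-base alignment vs two 150-base ones
  lens <- c(gA = 600)
  fam <- c(gA = "f")
  whole <- data.frame(read_id = "r1", marker_id = "gA", mapq = 42L,
                      read_length = 300L, aligned_start = 100L,
                      aligned_end = 400L)
  split2 <- data.frame(read_id = c("r1a", "r1b"), marker_id = "gA",
                       mapq = 42L, read_length = 150L,
                       aligned_start = c(100L, 250L),
                       aligned_end = c(250L, 400L))
  d1 <- gene_depths(whole, lens)
  d2 <- gene_depths(split2, lens)
  expect_equal(family_coverage(d1, lens, fam), family_coverage(d2, lens, fam))
})

test_that("presence/absence calling follows the coverage-curve rules", {
  # flat curve at 4.0 over 1000 families: detectable, all present
  cov <- setNames(rep(4, 1000), sprintf("f%04d", 1:1000))
  call <- call_presence_absence(cov)
  expect_true(call$detectable)
  expect_equal(call$plateau, 4)
  expect_true(all(call$presence))

  # plateau 1.2 < min_coverage 2: not detectable
  call <- call_presence_absence(cov * 0.3)
  expect_false(call$detectable)
  expect_null(call$presence)

  # steeply decaying curve whose left edge is twice the median
  k <- 100
  cov <- setNames(c(rep(8, 25), rep(4, 50), rep(3.5, 25)),
                  sprintf("f%03d", 1:k))
  call <- call_presence_absence(cov)
  expect_equal(call$left_edge, 8)
  expect_false(call$detectable)   # 8 > 1.25 * 4

  # mixed present/absent families at uniform depth
  cov <- setNames(c(rep(4, 80), rep(0, 20)), sprintf("f%03d", 1:100))
  call <- call_presence_absence(cov)
  expect_true(call$detectable)
  expect_equal(sum(call$presence), 80L)
  expect_equal(unname(call$presence[c("f001", "f100")]), c(TRUE, FALSE))

  # all-zero vector
  expect_false(call_presence_absence(setNames(numeric(5),
                                              letters[1:5]))$detectable)
})

test_that("raising a family's coverage never flips it present-to-absent", {
  set.seed(31)
  cov <- setNames(c(runif(60, 3, 5), runif(20, 0, 1), rep(0, 20)),
                  sprintf("f%03d", 1:100))
  base <- call_presence_absence(cov)
  expect_true(base$detectable)
  for (f in sample(names(cov), 25)) {
    for (delta in c(0.5, 2, 10)) {
      cov2 <- cov
      cov2[f] <- cov2[f] + delta
      call2 <- call_presence_absence(cov2)
      if (base$detectable && call2$detectable && base$presence[[f]])
        expect_true(call2$presence[[f]])
    }
  }
})

test_that("presence matrix assembly skips non-detectable samples", {
  cov_hi <- setNames(rep(4, 30), sprintf("f%02d", 1:30))
  cov_lo <- cov_hi * 0.2
  calls <- list(sA = call_presence_absence(cov_hi),
                sB = call_presence_absence(cov_lo),
                sC = call_presence_absence(cov_hi))
  pam <- presence_absence_matrix(calls)
  expect_equal(colnames(pam$matrix), c("sA", "sC"))
  expect_equal(pam$detectable, c(sA = TRUE, sB = FALSE, sC = TRUE))
})

test_that("matrix pre-filter applies both rounds", {
  set.seed(32)
  m <- matrix(rbinom(30 * 20, 1, 0.5), 30, 20,
              dimnames = list(sprintf("f%02d", 1:30),
                              sprintf("s%02d", 1:20)))
  m[1, ] <- 1               # absent in 0 <= 5 samples -> dropped
  m[2, ] <- c(1, rep(0, 19))  # present in < 2 -> dropped
  f <- prefilter_presence_matrix(m)
  expect_false(any(c("f01", "f02") %in% rownames(f)))
  frac <- rowMeans(f)
  expect_true(all(frac >= 0.05 & frac <= 0.95))
})

test_that("Jaccard/Ward clustering matches a naive agglomeration oracle", {
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1,
                1, 0, 1, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  cl <- cluster_families(m, k_rows = 2)
  # identical rows f1/f2 at distance 0 merge first
  expect_equal(sort(cl$row_hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$row_hclust$height[1], 0)
  expect_equal(cl$row_clusters[["f1"]], cl$row_clusters[["f2"]])
  # complementary rows are at Jaccard distance 1
  expect_equal(as.matrix(dist(m, method = "binary"))["f1", "f3"], 1)

  # naive O(n^3) Ward.D2 (Lance-Williams) agreement on a random matrix
  set.seed(33)
  mm <- matrix(rbinom(7 * 6, 1, 0.5), 7, 6,
               dimnames = list(paste0("f", 1:7), paste0("s", 1:6)))
  mm <- mm[!duplicated(mm), ]
  naive_ward <- function(d0) {
    d <- as.matrix(d0); diag(d) <- Inf
    n <- nrow(d); size <- rep(1, n); active <- rep(TRUE, n)
    heights <- numeric(0)
    for (step in seq_len(n - 1)) {
      idx <- which(d == min(d[active, active]), arr.ind = TRUE)[1, ]
      i <- min(idx); j <- max(idx)
      heights <- c(heights, d[i, j])
      for (k in which(active)) {
        if (k %in% c(i, j)) next
        d[i, k] <- d[k, i] <- sqrt(
          ((size[i] + size[k]) * d[i, k]^2 +
             (size[j] + size[k]) * d[j, k]^2 -
             size[k] * d[i, j]^2) / (size[i] + size[j] + size[k]))
      }
      size[i] <- size[i] + size[j]; active[j] <- FALSE
      d[j, ] <- d[, j] <- Inf
    }
    heights
  }
  hc <- cluster_families(mm)$row_hclust
  expect_equal(hc$height, naive_ward(dist(mm, method = "binary")),
               tolerance = 1e-9)

  expect_error(cluster_families(m[1, , drop = FALSE]), "degenerate")
})

test_that("locus compactness statistic and empirical p behave as expected", {
  # 20-gene contig; genes 1-3 adjacent with no gaps, the rest spaced out
  starts <- c(0, 300, 600, seq(2000, by = 1500, length.out = 17))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), contig = "c1",
                      start = starts, end = starts + 300)
  cluster <- genes[1:3, ]
  gt <- gene_cluster_pvalue(cluster, genes, n_permutations = 500, seed = 5)
  expect_equal(gt$statistic, 1.0)
  expect_equal(gt$p_value, 1 / 501)  # no random triple is gap-free

  scattered <- genes[c(1, 10, 20), ]
  gt2 <- gene_cluster_pvalue(scattered, genes, n_permutations = 500,
                             seed = 5)
  expect_lt(gt2$statistic, 0.1)
  expect_gt(gt2$p_value, 0.5)

  # agreement with exhaustive enumeration when C(n, k) is small
  set.seed(34)
  st10 <- sort(sample(0:5000, 10)) * 3L
  g10 <- data.frame(gene_id = sprintf("h%02d", 1:10), contig = "c1",
                    start = st10, end = st10 + 200L)
  cl10 <- g10[c(2, 3, 5), ]
  stat <- function(g) sum(g$end - g$start) / (max(g$end) - min(g$start))
  all_stats <- combn(10, 3, function(ix) stat(g10[ix, ]))
  exact_p <- mean(all_stats >= stat(cl10))
  est <- gene_cluster_pvalue(cl10, g10, n_permutations = 2000, seed = 6)
  expect_equal(est$p_value, exact_p, tolerance = 0.05)

  multi <- cluster; multi$contig <- c("c1", "c1", "c2")
  expect_warning(out <- gene_cluster_pvalue(multi, genes), "contig")
  expect_true(is.na(out$p_value))
})

test_that("null locus p-values are approximately uniform", {
  set.seed(35)
  starts <- cumsum(sample(200:800, 30))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30), contig = "c1",
                      start = starts, end = starts + sample(150:450, 30))
  pvals <- vapply(1:150, function(i) {
    cl <- genes[sample(30, 4), ]
    gene_cluster_pvalue(cl, genes, n_permutations = 199,
                        seed = 100 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
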