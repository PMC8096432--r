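# Pangenome-based strain typing: gene-family coverage normalization,
# presence/absence calling from the sorted coverage curve, matrix
# clustering, and the gene-cluster locus-compactness test.

#' Gene-family coverage of one sample
#'
#' Family coverage is the depth-weighted base count of the family's
#' genes divided by the family's mean gene length:
#' `cov(F) = sum(depth_g * len_g) / mean(len_g)`.  This base-count
#' reading is invariant to splitting a gene's alignments into fragments.
#' Genes absent from the alignments contribute depth 0.
#'
#' @param depths named numeric vector `gene_id -> depth` (genes missing
#'   from the vector count as 0).
#' @param gene_lengths named numeric vector `gene_id -> length` (nt,
#'   positive), covering the full pangenome.
#' @param family_of named character vector `gene_id -> family_id`.
#' @return named numeric vector `family_id -> normalized coverage`.
#' @export
family_coverage <- function(depths, gene_lengths, family_of) {
  stopifnot(all(gene_lengths > 0),
            all(names(gene_lengths) %in% names(family_of)))
  genes <- names(gene_lengths)
  d <- setNames(numeric(length(genes)), genes)
  known <- intersect(names(depths), genes)
  d[known] <- depths[known]
  fam <- family_of[genes]
  if (any(is.na(fam))) stop("gene without family assignment")
  base_sum <- tapply(d * gene_lengths, fam, sum)
  mean_len <- tapply(gene_lengths, fam, mean)
  if (any(tapply(genes, fam, length) == 0)) stop("empty family")
  out <- as.numeric(base_sum / mean_len)
  setNames(out, names(base_sum))
}

#' Call gene-family presence/absence from a coverage curve
#'
#' Family coverages are sorted descending into the sample's coverage
#' curve.  The plateau level is the median of the nonzero part of the
#' curve.  The sample is *detectable* (i.e. carries enough of the
#' species' strain to type) when the plateau is at least `min_coverage`
#' and the curve is flat enough around the plateau: the value at the
#' left edge (rank `0.25 * k` of the `k` nonzero families) must not
#' exceed `left_max * plateau` and the value at the right edge (rank
#' `0.75 * k`) must be at least `right_min * plateau`.  In a detectable
#' sample a family is present when its coverage reaches half the
#' plateau, with an absolute floor of `min_coverage / 2`.
#'
#' @param coverage named numeric vector over the full pangenome
#'   (from [family_coverage()]).
#' @param min_coverage minimum plateau level (default 2).
#' @param left_max,right_min plateau-edge multipliers (defaults 1.25 and
#'   0.75).
#' @param presence_frac presence cutoff as a fraction of the plateau
#'   (default 0.5).
#' @return list of class `pa_call`: `detectable`, `presence` (named
#'   logical; `NULL` when not detectable), `plateau`, `left_edge`,
#'   `right_edge`, `threshold`.
#' @export
call_presence_absence <- function(coverage, min_coverage = 2,
                                  left_max = 1.25, right_min = 0.75,
                                  presence_frac = 0.5) {
  curve <- sort(coverage, decreasing = TRUE)
  nz <- curve[curve > 0]
  k <- length(nz)
  if (k == 0L)
    return(structure(list(detectable = FALSE, presence = NULL,
                          plateau = 0, left_edge = 0, right_edge = 0,
                          threshold = NA_real_), class = "pa_call"))
  plateau <- unname(median(nz))
  left_edge <- unname(nz[max(1L, ceiling(0.25 * k))])
  right_edge <- unname(nz[max(1L, ceiling(0.75 * k))])
  detectable <- plateau >= min_coverage &&
    left_edge <= left_max * plateau &&
    right_edge >= right_min * plateau
  threshold <- max(plateau * presence_frac, min_coverage / 2)
  presence <- if (detectable) coverage >= threshold else NULL
  structure(list(detectable = detectable, presence = presence,
                 plateau = plateau, left_edge = left_edge,
                 right_edge = right_edge, threshold = threshold),
            class = "pa_call")
}

#' @export
print.pa_call <- function(x, ...) {
  if (x$detectable)
    cat(sprintf(
      "<pa_call  detectable, plateau %.3g, %d/%d families present>\n",
      x$plateau, sum(x$presence), length(x$presence)))
  else
    cat(sprintf("<pa_call  not detectable (plateau %.3g)>\n", x$plateau))
  invisible(x)
}

#' Assemble a presence/absence matrix over samples
#'
#' @param calls named list `sample_id -> pa_call`; columns are emitted
#'   only for detectable samples.
#' @return list: `matrix` (binary families x samples), `detectable`
#'   (named logical over all samples).
#' @export
presence_absence_matrix <- function(calls) {
  det <- vapply(calls, function(x) x$detectable, logical(1))
  cols <- lapply(calls[det], function(x) as.integer(x$presence))
  m <- if (length(cols)) {
    fam <- names(calls[det][[1L]]$presence)
    do.call(cbind, lapply(cols, function(v) setNames(v, fam)))
  } else matrix(integer(0), 0L, 0L)
  if (length(cols)) dimnames(m) <- list(names(calls[det][[1L]]$presence),
                                        names(calls)[det])
  list(matrix = m, detectable = det)
}

#' Pre-filter a presence/absence matrix for clustering
#'
#' Two rounds: first drop families present in fewer than `min_present`
#' samples or absent from `max_absent` or fewer samples; then drop
#' families present in more than `high_frac` or less than `low_frac` of
#' the remaining samples.
#'
#' @param m binary matrix, families x samples.
#' @param min_present,max_absent round-1 thresholds (defaults 2 and 5).
#' @param high_frac,low_frac round-2 thresholds (defaults 0.95, 0.05).
#' @return the filtered matrix.
#' @export
prefilter_presence_matrix <- function(m, min_present = 2L, max_absent = 5L,
                                      high_frac = 0.95, low_frac = 0.05) {
  pres <- rowSums(m)
  abs_ <- ncol(m) - pres
  m <- m[pres >= min_present & abs_ > max_absent, , drop = FALSE]
  frac <- rowMeans(m)
  m[frac <= high_frac & frac >= low_frac, , drop = FALSE]
}

#' Cluster a presence/absence matrix
#'
#' Jaccard distances between family rows and between sample columns,
#' agglomerated with Ward's criterion; leaf order (and hence the
#' reordered matrix) is deterministic for a given input.
#'
#' @param m binary matrix, families x samples (pre-filter with
#'   [prefilter_presence_matrix()]).
#' @param k_rows,k_cols number of flat clusters to cut (default 2).
#' @return list: `row_hclust`, `col_hclust`, `row_clusters`,
#'   `col_clusters`, `ordered` (matrix with rows/cols in dendrogram
#'   order).
#' @export
cluster_families <- function(m, k_rows = 2L, k_cols = 2L) {
  if (nrow(m) < 2L) stop("degenerate matrix: need at least 2 family rows")
  dr <- stats::dist(m, method = "binary")
  hc_r <- stats::hclust(dr, method = "ward.D2")
  out <- list(row_hclust = hc_r,
              row_clusters = stats::cutree(hc_r, k = min(k_rows, nrow(m))))
  if (ncol(m) >= 2L) {
    dc <- stats::dist(t(m), method = "binary")
    hc_c <- stats::hclust(dc, method = "ward.D2")
    out$col_hclust <- hc_c
    out$col_clusters <- stats::cutree(hc_c, k = min(k_cols, ncol(m)))
    out$ordered <- m[hc_r$order, hc_c$order, drop = FALSE]
  } else {
    out$ordered <- m[hc_r$order, , drop = FALSE]
  }
  out
}

#' Locus-compactness test for a gene cluster
#'
#' Tests whether a group of co-occurring gene families sits
#' significantly close together along its contig.  The statistic is the
#' ratio of the summed gene lengths to the group's total span on the
#' contig (1 for perfectly adjacent genes).  The null distribution is
#' obtained by drawing random same-size gene sets from the contig and
#' the empirical p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + n_permutations)`.
#'
#' @param cluster_genes data.frame `gene_id`, `contig`, `start`, `end`
#'   for the cluster members (all on one contig).
#' @param contig_genes data.frame with the same columns for *all* genes
#'   of that contig.
#' @param n_permutations number of null draws (>= 100; default 999).
#' @param seed RNG seed for the permutation draws.
#' @return list of class `gene_cluster_test`: `statistic`, `p_value`,
#'   `n_permutations`.
#' @export
gene_cluster_pvalue <- function(cluster_genes, contig_genes,
                                n_permutations = 999L, seed = 1L) {
  stopifnot(n_permutations >= 100L)
  if (length(unique(cluster_genes$contig)) != 1L) {
    warning("cluster genes span multiple contigs; statistic undefined")
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          n_permutations = n_permutations),
                     class = "gene_cluster_test"))
  }
  contig_genes <- contig_genes[contig_genes$contig ==
                                 cluster_genes$contig[1L], , drop = FALSE]
  stat <- function(g) sum(g$end - g$start) / (max(g$end) - min(g$start))
  observed <- stat(cluster_genes)
  k <- nrow(cluster_genes)
  if (k > nrow(contig_genes)) stop("cluster larger than contig gene set")
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i)
    stat(contig_genes[sample.int(nrow(contig_genes), k), , drop = FALSE]),
    numeric(1))
  structure(list(statistic = observed,
                 p_value = (1 + sum(null >= observed)) /
                   (1 + n_permutations),
                 n_permutations = n_permutations),
            class = "gene_cluster_test")
}

#' @export
print.gene_cluster_test <- function(x, ...) {
  cat(sprintf("<gene_cluster_test  statistic %.4f, p = %.4g (%d perms)>\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
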