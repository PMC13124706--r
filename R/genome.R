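#' Consecutive TSS distances within chromosomes
#'
#' Sorts genes by TSS within each chromosome and returns the consecutive
#' differences; chromosomes holding a single gene contribute nothing and
#' cross-chromosome pairs are never formed.
#'
#' @param gt a `gene_table` (or subset).
#' @return numeric vector of distances in base pairs.
#' @export
neighbor_distances <- function(gt) {
  if (nrow(gt) < 2) stop("neighbor_distances: need >= 2 genes")
  unlist(lapply(split(gt$tss, gt$chrom), function(tss) {
    if (length(tss) < 2) return(numeric())
    diff(sort(tss))
  }), use.names = FALSE)
}

# Count maximal chains of >= min_genes sorted TSS with consecutive gaps
# <= max_gap. `tss_by_chrom` is a list of sorted numeric vectors.
count_chain_clusters <- function(tss_by_chrom, max_gap, min_genes) {
  total <- 0L
  for (tss in tss_by_chrom) {
    if (length(tss) < min_genes) next
    ok <- diff(tss) <= max_gap
    r <- rle(ok)
    total <- total + sum(r$values & r$lengths >= (min_genes - 1L))
  }
  total
}

#' Detect genomic clusters of genes
#'
#' A cluster is a maximal run of TSS-sorted genes on one chromosome whose
#' consecutive TSS gaps are all at most `max_gap`, containing at least
#' `min_genes` genes. The rule and both parameters are configurable; the
#' defaults (100 kb, 3 genes) give clusters of the size scale typically
#' reported for co-regulated loci.
#'
#' @param gt a `gene_table` subset (e.g. the DE genes).
#' @param max_gap maximum consecutive TSS gap in bp.
#' @param min_genes minimum genes per cluster.
#' @return list of class `cluster_result`: `clusters` (data.frame with
#'   `chrom`, `gene_ids` list-column, `span`), `n_clusters`,
#'   `n_genes_in_clusters`.
#' @export
detect_clusters <- function(gt, max_gap = 100e3, min_genes = 3) {
  clusters <- list()
  for (chrom in unique(gt$chrom)) {
    sub <- gt[gt$chrom == chrom, , drop = FALSE]
    ord <- order(sub$tss)
    sub <- sub[ord, , drop = FALSE]
    if (nrow(sub) < min_genes) next
    ok <- diff(sub$tss) <= max_gap
    r <- rle(ok)
    idx_end <- cumsum(r$lengths)
    idx_start <- c(1L, utils::head(idx_end, -1) + 1L)
    for (j in seq_along(r$values)) {
      if (r$values[j] && r$lengths[j] >= min_genes - 1L) {
        members <- sub[idx_start[j]:(idx_end[j] + 1L), , drop = FALSE]
        clusters[[length(clusters) + 1L]] <- data.frame(
          chrom = chrom,
          gene_ids = I(list(members$gene_id)),
          span = max(members$tss) - min(members$tss),
          stringsAsFactors = FALSE)
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters)
              else data.frame(chrom = character(), gene_ids = I(list()),
                              span = numeric())
  res <- list(clusters = clusters, n_clusters = nrow(clusters),
              n_genes_in_clusters = sum(lengths(clusters$gene_ids)))
  class(res) <- "cluster_result"
  res
}

#' Permutation null for the DE gene cluster count
#'
#' Draws `n_perm` random subsets of the non-DE genes, each of the same
#' size as the DE set, counts clusters in each draw, and reports the
#' add-one upper-tail empirical p-value of the observed DE cluster count.
#'
#' @param gt the full `gene_table` of expressed genes.
#' @param de_flags logical vector along `gt` rows.
#' @param max_gap,min_genes cluster rule (see [detect_clusters()]).
#' @param n_perm number of random subsets.
#' @param seed RNG seed.
#' @return `cluster_result` with extra elements `null_counts` and
#'   `empirical_p`.
#' @export
cluster_permutation_null <- function(gt, de_flags, max_gap = 100e3,
                                     min_genes = 3, n_perm = 1000,
                                     seed = 1L) {
  n_de <- sum(de_flags)
  non_de <- which(!de_flags)
  if (length(non_de) < n_de)
    stop("cluster_permutation_null: insufficient non-DE genes")
  obs <- detect_clusters(gt[de_flags, , drop = FALSE], max_gap, min_genes)
  # pre-split sorted TSS by chromosome once; permutations subsample indices
  chrom_f <- factor(gt$chrom)
  ord <- order(chrom_f, gt$tss)
  tss_sorted <- gt$tss[ord]
  chrom_sorted <- chrom_f[ord]
  is_non_de_sorted <- !de_flags[ord]
  pos_non_de <- which(is_non_de_sorted)
  chrom_int <- as.integer(chrom_sorted)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    take <- sort(sample(pos_non_de, n_de))
    tss_by_chrom <- split(tss_sorted[take], chrom_int[take])
    count_chain_clusters(tss_by_chrom, max_gap, min_genes)
  }, integer(1))
  obs$null_counts <- null_counts
  obs$empirical_p <- empirical_p(obs$n_clusters, null_counts)
  obs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' DE enrichment in a genomic region
#'
#' Builds the 2x2 table of (TSS within region vs outside) against (DE vs
#' not) over the supplied genes and applies the one-sided (greater)
#' Fisher's exact test. The default region is the HLA locus
#' (chr6:28,510,120-33,480,577 on hg38, 1-based inclusive).
#'
#' @param gt `gene_table` of expressed genes.
#' @param de_flags logical vector along `gt`.
#' @param region list with `chrom`, `start`, `end` (1-based inclusive).
#' @return A `cerna_test` with the 2x2 `table` extra.
#' @export
region_enrichment <- function(gt, de_flags,
                              region = list(chrom = "chr6",
                                            start = 28510120,
                                            end = 33480577)) {
  if (region$end < region$start) stop("region_enrichment: empty region")
  inside <- gt$chrom == region$chrom &
    gt$tss >= region$start - 1 & gt$tss <= region$end - 1
  tab <- matrix(c(sum(inside & de_flags), sum(inside & !de_flags),
                  sum(!inside & de_flags), sum(!inside & !de_flags)),
                2, 2, byrow = TRUE)
  res <- fisher_exact(tab, "greater")
  res$table <- tab
  res
}

#' DE enrichment near association loci
#'
#' A gene is "near" when the minimum distance between its TSS and any
#' locus on the same chromosome is at most `window`. One-sided Fisher test
#' of near x DE.
#'
#' @param gt `gene_table` of expressed genes.
#' @param de_flags logical vector along `gt`.
#' @param loci data.frame with `chrom` and 0-based `pos0` (see
#'   [read_loci()]).
#' @param window distance window in bp.
#' @return A `cerna_test` with `table` and `near` extras.
#' @export
locus_proximity_enrichment <- function(gt, de_flags, loci, window = 100e3) {
  if (is.null(loci) || nrow(loci) == 0)
    stop("locus_proximity_enrichment: empty locus list")
  near <- rep(FALSE, nrow(gt))
  for (chrom in unique(loci$chrom)) {
    pos <- loci$pos0[loci$chrom == chrom]
    sel <- gt$chrom == chrom
    if (!any(sel)) next
    d <- vapply(gt$tss[sel], function(t) min(abs(t - pos)), numeric(1))
    near[sel] <- d <= window
  }
  tab <- matrix(c(sum(near & de_flags), sum(near & !de_flags),
                  sum(!near & de_flags), sum(!near & !de_flags)),
                2, 2, byrow = TRUE)
  res <- fisher_exact(tab, "greater")
  res$table <- tab
  res$near <- near
  res
}

#' DE fraction of coding genes by distance to the nearest DE lncRNA
#'
#' Each coding gene falls in exactly one bin: `within` when its gene body
#' overlaps a DE lncRNA gene body, otherwise `nearby`
#' (TSS distance < nearby_kb), `close` (nearby_kb to close_kb) or `far`
#' (> close_kb; also used when no DE lncRNA shares the chromosome). Each
#' bin's DE fraction comes with a 95% Wilson score interval and the bins
#' are compared by chi-square.
#'
#' @param coding_gt coding `gene_table`.
#' @param coding_de logical DE flags along `coding_gt`.
#' @param de_lnc_gt `gene_table` of DE lncRNAs.
#' @param nearby_kb,close_kb bin edges in kb.
#' @return list with `bins` data.frame (bin, n, n_de, fraction, lo, hi)
#'   and `test` (`cerna_test`), plus per-gene `bin` assignment.
#' @export
distance_binned_de_fraction <- function(coding_gt, coding_de, de_lnc_gt,
                                        nearby_kb = 100, close_kb = 500) {
  if (!nrow(coding_gt) || !nrow(de_lnc_gt))
    stop("distance_binned_de_fraction: empty gene set")
  gr_c <- as_granges(coding_gt)
  gr_l <- as_granges(de_lnc_gt)
  ov <- GenomicRanges::findOverlaps(gr_c, gr_l, ignore.strand = TRUE)
  within <- seq_len(nrow(coding_gt)) %in% S4Vectors::queryHits(ov)
  # nearest TSS distance per coding gene
  dist <- rep(Inf, nrow(coding_gt))
  for (chrom in unique(de_lnc_gt$chrom)) {
    pos <- de_lnc_gt$tss[de_lnc_gt$chrom == chrom]
    sel <- coding_gt$chrom == chrom
    if (!any(sel)) next
    dist[sel] <- vapply(coding_gt$tss[sel],
                        function(t) min(abs(t - pos)), numeric(1))
  }
  bin <- ifelse(within, "within",
         ifelse(dist < nearby_kb * 1e3, "nearby",
         ifelse(dist <= close_kb * 1e3, "close", "far")))
  bin <- factor(bin, levels = c("within", "nearby", "close", "far"))
  n <- as.vector(table(bin))
  n_de <- as.vector(table(bin[coding_de]))
  frac <- ifelse(n > 0, n_de / n, NA_real_)
  ci <- t(vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(c(NA_real_, NA_real_))
    wilson_interval(n_de[i], n[i])
  }, numeric(2)))
  keep <- n > 0
  tab <- rbind(n_de[keep], (n - n_de)[keep])
  test <- if (sum(keep) >= 2 && all(rowSums(tab) > 0))
    chisq_2xk(tab, yates = FALSE) else NULL
  list(bins = data.frame(bin = levels(bin), n = n, n_de = n_de,
                         fraction = frac, lo = ci[, 1], hi = ci[, 2]),
       test = test, bin = bin)
}

# 95% Wilson score interval for a binomial proportion
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
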