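toy_gt <- function(tss, chrom = "chr1", prefix = "g") {
  gene_table(sprintf("%s%d", prefix, seq_along(tss)), "coding", chrom,
             start = tss, end = tss + 1000, strand = "+")
}

test_that("neighbour distances are per-chromosome consecutive TSS
           differences", {
  gt <- toy_gt(c(0, 50e3, 200e3))
  expect_equal(sort(neighbor_distances(gt)), c(50e3, 150e3))
  gt2 <- gene_table(c("a", "b"), "coding", c("chr1", "chr2"),
                    c(0, 0), c(1e3, 1e3), c("+", "+"))
  expect_length(neighbor_distances(gt2), 0)
  set.seed(9)
  gt3 <- toy_gt(sample.int(1e6, 40), chrom = rep(c("chr1", "chr2"), 20))
  expect_length(neighbor_distances(gt3), 40 - 2)
  expect_error(neighbor_distances(gt3[1, ]), ">= 2")
})

test_that("cluster detection finds maximal chains with the gap and size
           rules", {
  gt <- toy_gt(c(0, 60e3, 130e3, 500e3))
  res <- detect_clusters(gt, max_gap = 100e3, min_genes = 3)
  expect_equal(res$n_clusters, 1)
  expect_equal(res$clusters$gene_ids[[1]], c("g1", "g2", "g3"))
  expect_equal(res$n_genes_in_clusters, 3)
  expect_equal(detect_clusters(gt, min_genes = 5)$n_clusters, 0)
  gt2 <- toy_gt(c(0, 200e3, 400e3, 600e3))
  expect_equal(detect_clusters(gt2)$n_clusters, 0)
  # order independence
  set.seed(4)
  gt3 <- toy_gt(sample.int(2e6, 50))
  shuffled <- gt3[sample.int(50), ]
  expect_equal(detect_clusters(gt3)$n_clusters,
               detect_clusters(shuffled)$n_clusters)
})

test_that("permutation null bounds and planted-cluster significance", {
  co <- small_cohort()
  gt <- co$annotation
  gt <- gt[gt$biotype != "miRNA", ]
  tg <- co$truth$genes
  de <- tg$is_de_truth[match(gt$gene_id, tg$gene_id)] %in% TRUE
  res <- cluster_permutation_null(gt, de, n_perm = 200, seed = 5)
  expect_gte(res$n_clusters, 1)
  expect_lte(res$empirical_p, 0.05)
  expect_length(res$null_counts, 200)
  one <- cluster_permutation_null(gt, de, n_perm = 1, seed = 5)
  expect_true(one$empirical_p %in% c(0.5, 1))
  expect_error(cluster_permutation_null(gt, rep(TRUE, nrow(gt))),
               "insufficient")
})

test_that("region enrichment builds the Fisher table from TSS
           membership", {
  gt <- toy_gt(c(10, 20, 1e6, 2e6), chrom = "chr6")
  de <- c(TRUE, TRUE, FALSE, FALSE)
  res <- region_enrichment(gt, de, region = list(chrom = "chr6",
                                                 start = 1, end = 1000))
  expect_identical(res$odds_ratio, Inf)
  expect_equal(res$table, matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(res$p, fisher_exact(res$table, "greater")$p)
  # balanced toy: no enrichment
  res2 <- region_enrichment(gt, c(TRUE, FALSE, TRUE, FALSE),
                            region = list(chrom = "chr6", start = 1,
                                          end = 1000))
  expect_equal(res2$odds_ratio, 1)
  expect_gte(res2$p, 0.5)
  expect_error(region_enrichment(gt, de,
                                 region = list(chrom = "chr6",
                                               start = 10, end = 5)),
               "empty region")
})

test_that("locus proximity uses the same-chromosome TSS window", {
  gt <- toy_gt(c(100, 5e5, 1e6))
  loci <- data.frame(chrom = "chr1", pos0 = 100)
  res <- locus_proximity_enrichment(gt, c(TRUE, FALSE, FALSE), loci,
                                    window = 0)
  expect_equal(res$near, c(TRUE, FALSE, FALSE))
  expect_error(locus_proximity_enrichment(gt, rep(TRUE, 3),
                                          loci[0, , drop = FALSE]),
               "empty locus list")
  # a locus at a planted cluster centre is enriched on the cohort
  co <- small_cohort()
  gt2 <- co$annotation[co$annotation$biotype != "miRNA", ]
  tg <- co$truth$genes
  de <- tg$is_de_truth[match(gt2$gene_id, tg$gene_id)] %in% TRUE
  res2 <- locus_proximity_enrichment(gt2, de, co$loci, window = 100e3)
  expect_lt(res2$p, 0.05)
})

test_that("distance bins partition the coding genes with the stated
           thresholds", {
  lnc <- gene_table("l1", "lncRNA", "chr1", 1e6, 1.1e6, "+")
  coding <- gene_table(c("in_body", "near", "close", "far", "other_chr"),
                       "coding",
                       c("chr1", "chr1", "chr1", "chr1", "chr2"),
                       start = c(1.05e6, 0.95e6, 1.35e6, 2.2e6, 1e6),
                       end = c(1.06e6, 0.96e6, 1.36e6, 2.21e6, 1.01e6),
                       strand = "+")
  res <- distance_binned_de_fraction(coding, c(TRUE, rep(FALSE, 4)), lnc)
  expect_equal(as.character(res$bin),
               c("within", "nearby", "close", "far", "far"))
  expect_equal(sum(res$bins$n), nrow(coding))
  expect_true(all(res$bins$fraction >= res$bins$lo - 1e-9, na.rm = TRUE))
  # 250 kb TSS distance lands in "close"
  g250 <- gene_table("x", "coding", "chr1", 1.25e6, 1.26e6, "+")
  res2 <- distance_binned_de_fraction(g250, FALSE, lnc)
  expect_equal(as.character(res2$bin), "close")
})

test_that("the permutation null is calibrated under exchangeable labels", {
  # dense geometry so the cluster count is well spread
  set.seed(12)
  tss <- cumsum(rexp(1200, 1 / 60e3))
  gt <- toy_gt(tss)
  ps <- vapply(1:200, function(i) {
    de <- rep(FALSE, 1200)
    de[sample.int(1200, 400)] <- TRUE
    cluster_permutation_null(gt, de, n_perm = 99,
                             seed = 1000 + i)$empirical_p
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_gte(mean(ps <= 0.05), 0.01)
  expect_lte(mean(ps <= 0.05), 0.10)
})
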