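test_that("blocked correlation engine equals the naive per-pair oracle
           and is block-size invariant", {
  set.seed(14)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("s%d", 1:20)))
  em <- toy_em(m, scale = "log2")
  em$scale <- "adjusted"
  lnc <- rownames(m)[1:20]
  cod <- rownames(m)[21:50]
  cr <- pairwise_correlations(em, lnc, cod, block_size = 7)
  oracle <- naive_corr_table(m, lnc, cod)
  key <- paste(cr$pairs$lnc_id, cr$pairs$coding_id)
  okey <- paste(oracle$lnc_id, oracle$coding_id)
  oracle <- oracle[match(key, okey), ]
  expect_equal(cr$pairs$r, oracle$r, tolerance = 1e-10)
  expect_equal(cr$pairs$p, oracle$p, tolerance = 1e-10)
  expect_equal(cr$m_tested, 600)
  cr1 <- pairwise_correlations(em, lnc, cod, block_size = 1)
  expect_equal(cr$pairs, cr1$pairs, tolerance = 1e-12)
})

test_that("per-pair results match pearson_corr exactly and a duplicated
           gene is perfectly correlated", {
  set.seed(15)
  m <- matrix(rnorm(5 * 30), 5, 30)
  rownames(m) <- c("l1", "l2", "g1", "g2", "g3")
  m <- rbind(m, l3 = m["g1", ])  # lncRNA duplicating a coding gene
  em <- toy_em(m, scale = "log2"); em$scale <- "adjusted"
  cr <- pairwise_correlations(em, c("l1", "l2", "l3"),
                              c("g1", "g2", "g3"))
  dup <- cr$pairs[cr$pairs$lnc_id == "l3" & cr$pairs$coding_id == "g1", ]
  expect_equal(dup$r, 1)
  expect_equal(dup$p, 0)
  expect_true(dup$significant)
  one <- cr$pairs[cr$pairs$lnc_id == "l1" & cr$pairs$coding_id == "g2", ]
  ref <- pearson_corr(m["l1", ], m["g2", ])
  expect_equal(one$r, ref$r, tolerance = 1e-12)
  expect_equal(one$p, ref$p, tolerance = 1e-12)
  expect_equal(one$p_bonf, min(1, ref$p * 9), tolerance = 1e-12)
})

test_that("zero-variance genes are dropped but still counted in the
           Bonferroni family", {
  m <- rbind(l1 = rnorm(10), l2 = rep(3, 10), g1 = rnorm(10),
             g2 = rnorm(10))
  em <- toy_em(m, scale = "log2"); em$scale <- "adjusted"
  expect_message(cr <- pairwise_correlations(em, c("l1", "l2"),
                                             c("g1", "g2")),
                 "zero variance")
  expect_equal(cr$m_tested, 4)
  expect_equal(nrow(cr$pairs), 2)
  expect_equal(cr$dropped, "l2")
})

test_that("positivity test delegates to the exact binomial", {
  toy <- toy_network_inputs()
  cr <- toy$cr
  cr$pairs$significant <- TRUE
  cr$pairs$r <- c(0.8, 0.3, 0.9, 0.6, -0.7, -0.2)
  res <- positivity_test(cr)
  expect_equal(res$p, binomial_test(4, 6, 0.5)$p)
  expect_equal(res$positive_fraction, 4 / 6)
  cr$pairs$significant <- FALSE
  expect_error(positivity_test(cr), "zero significant")
})

test_that("cis-coupled neighbour pairs show stronger correlation than
           random pairs", {
  co <- small_cohort()
  em <- adjust_covariates(log2_quantile_normalize(co$em))
  ann <- co$annotation
  lnc <- intersect(ann$gene_id[ann$biotype %in% c("lncRNA",
                                                  "novel_lncRNA")],
                   rownames(em$values))
  cod <- intersect(ann$gene_id[ann$biotype == "coding"],
                   rownames(em$values))
  cr <- pairwise_correlations(em, lnc, cod)
  res <- adjacency_correlation_test(cr, ann, seed = 2)
  expect_lt(res$p, 0.01)
  expect_error(adjacency_correlation_test(cr, ann, window = 0),
               "no adjacent")
})

test_that("pairs sharing expressed miRNAs correlate more than pairs
           sharing none, and the predicate is symmetric under
           two-sided testing", {
  co <- small_cohort()
  em <- adjust_covariates(log2_quantile_normalize(co$em))
  ann <- co$annotation
  lnc <- intersect(ann$gene_id[ann$biotype %in% c("lncRNA",
                                                  "novel_lncRNA")],
                   rownames(em$values))
  cod <- intersect(ann$gene_id[ann$biotype == "coding"],
                   rownames(em$values))
  cr <- pairwise_correlations(em, lnc, cod)
  expressed <- filter_expressed_mirnas(co$mirna_tpm)
  res <- shared_mirna_correlation_test(cr, co$bindings$lnc,
                                       co$bindings$mrna, expressed)
  expect_lt(res$p, 0.01)
  empty <- co$bindings$lnc[0, ]
  expect_error(shared_mirna_correlation_test(cr, empty, empty, expressed),
               "empty")
})

test_that("correlated-lncRNA counts use the 0 / 1-10 / >10 bins and
           partition all coding genes", {
  cr <- list(pairs = data.frame(
    lnc_id = sprintf("l%d", 1:22),
    coding_id = c(rep("g1", 11), rep("g2", 10), "g3"),
    r = 0.9, p = 0, p_bonf = 0,
    significant = c(rep(TRUE, 21), FALSE)))
  class(cr) <- "corr_result"
  res <- correlated_lncrna_counts(cr, c("g1", "g2", "g3", "g4"),
                                  c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(res$counts), c(11, 10, 0, 0))
  expect_equal(as.character(res$bin), c("many", "few", "none", "none"))
  expect_equal(sum(res$table), 4)
})

test_that("no-structure cohorts yield (almost) no significant pairs at
           the Bonferroni level", {
  spec0 <- small_spec(seed = 19, coupling = 0, cis_strength = 0,
                      immune_loading_frac = 0, de_fraction = 1e-9,
                      cluster_beta = 1e-9,
                      regulator_activity_shift = -1e-9)
  co0 <- simulate_cohort(spec0)
  em <- adjust_covariates(log2_quantile_normalize(co0$em))
  ann <- co0$annotation
  lnc <- intersect(ann$gene_id[ann$biotype %in% c("lncRNA",
                                                  "novel_lncRNA")],
                   rownames(em$values))
  cod <- intersect(ann$gene_id[ann$biotype == "coding"],
                   rownames(em$values))
  cr <- pairwise_correlations(em, lnc, cod)
  expect_lte(sum(cr$pairs$p_bonf < 0.05), 3)
})
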