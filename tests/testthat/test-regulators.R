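fake_de <- function(gene_id, log2fc, p) {
  d <- data.frame(gene_id = gene_id, mean_case = 0, mean_control = 0,
                  log2fc = log2fc, p = p,
                  fdr = adjust_pvalues(p, "bh"),
                  is_de = abs(log2fc) >= log2(1.5) & p < 0.05,
                  stringsAsFactors = FALSE)
  class(d) <- c("de_result", "data.frame")
  d
}

test_that("gene ranking uses signed -log10 p with deterministic
           tie-breaks and a configurable metric", {
  de <- fake_de(c("b", "a", "c"), c(2, -2, 1), c(0.01, 0.01, 0.5))
  rk <- rank_genes(de)
  expect_equal(rk$gene_id, c("b", "c", "a"))
  expect_equal(rk$score, c(2, log10(2), -2), tolerance = 1e-12)
  # equal scores: lexicographic order
  de2 <- fake_de(c("z", "y"), c(1, 1), c(0.1, 0.1))
  expect_equal(rank_genes(de2)$gene_id, c("y", "z"))
  # p = 0 capped
  de3 <- fake_de("q", 1, 0)
  expect_equal(rank_genes(de3)$score, 320)
  expect_equal(rank_genes(de, metric = "log2fc")$gene_id,
               c("b", "c", "a"))
})

test_that("enrichment score equals the brute-force running sum on random
           instances", {
  set.seed(26)
  for (i in 1:40) {
    N <- sample(20:60, 1)
    m <- sample(3:10, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    hit <- rep(FALSE, N)
    hit[sample.int(N, m)] <- TRUE
    pos <- which(hit)
    es <- cernet:::gsea_es(pos, abs(scores[pos]), N)
    expect_equal(es, brute_es(scores, hit), tolerance = 1e-12)
  }
})

test_that("weight-zero extremes: top-k set scores ES 1, bottom-k set
           scores ES -1", {
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:20),
                       score = seq(10, -9), stringsAsFactors = FALSE)
  top <- gsea_preranked(ranked, sprintf("g%02d", 1:5), weight = 0,
                        n_perm = 50, seed = 1)
  expect_equal(top$es, 1)
  bottom <- gsea_preranked(ranked, sprintf("g%02d", 16:20), weight = 0,
                           n_perm = 50, seed = 1)
  expect_equal(bottom$es, -1)
  expect_error(gsea_preranked(ranked, c("g01", "g02"), n_perm = 10),
               "set too small")
  expect_error(gsea_preranked(ranked, ranked$gene_id, n_perm = 10),
               "covers the ranked universe")
})

test_that("null NES is centred near 1 in absolute value and p respects
           the permutation floor", {
  set.seed(27)
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:300),
                       score = sort(rnorm(300), decreasing = TRUE),
                       stringsAsFactors = FALSE)
  nes <- vapply(1:500, function(i) {
    g <- gsea_preranked(ranked, sample(ranked$gene_id, 15),
                        n_perm = 100, seed = i)
    abs(g$nes)
  }, numeric(1))
  expect_gt(mean(nes), 0.9)
  expect_lt(mean(nes), 1.1)
  g <- gsea_preranked(ranked, ranked$gene_id[1:10], n_perm = 100,
                      seed = 3)
  expect_gte(g$p, 1 / 101)
})

test_that("the interactor GSEA screen ranks planted regulators on top", {
  co <- small_cohort()
  res <- suppressMessages(run_pipeline(co, seed = 11))
  regs <- co$truth$regulators
  screen <- res$gsea_screen
  expect_true(all(regs %in% screen$lnc_id[seq_len(3)]))
  expect_true(all(screen$fdr[match(regs, screen$lnc_id)] < 0.01))
  expect_true(all(screen$nes[match(regs, screen$lnc_id)] > 0))
})

test_that("screen reproducibility and skipping of small interactor
           sets", {
  toy <- toy_network_inputs()
  net <- build_network(toy$lnc_b, toy$mrna_b, c("M1", "M2"), toy$cr)
  de <- fake_de(sprintf("G%d", 1:3), c(1, 0.5, -1), c(0.01, 0.2, 0.05))
  expect_message(out <- interactor_gsea_screen(net, de, n_perm = 20),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("interactor DE enrichment delegates to the hypergeometric
           oracle", {
  toy <- toy_network_inputs(r_values = c(L1.G1 = 0.8, L1.G2 = 0.8,
                                         L1.G3 = 0.8, L2.G1 = 0.1,
                                         L2.G2 = 0.1, L2.G3 = 0.1))
  lnc_b <- interaction_table(rep("M1", 4), c("L1", "G1", "G2", "G3"),
                             c("lncRNA", rep("mRNA", 3)),
                             "experimental")
  net <- build_network(lnc_b[1, ], lnc_b[-1, ], "M1", toy$cr)
  universe <- sprintf("G%d", 1:10)
  de <- fake_de(universe, c(rep(2, 5), rep(0, 5)),
                c(rep(1e-6, 5), rep(0.9, 5)))
  out <- interactor_de_enrichment(net, de, universe = universe)
  expect_equal(out$p, enum_hyper_upper(3, 3, 5, 10), tolerance = 1e-12)
  # zero DE interactors: p = 1
  de0 <- fake_de(universe, rep(0, 10), rep(0.9, 10))
  out0 <- interactor_de_enrichment(net, de0, universe = universe)
  expect_equal(out0$p, 1)
})

test_that("interactor fold-change contrast separates planted regulator
           targets from the rest", {
  co <- small_cohort()
  res <- suppressMessages(run_pipeline(co, seed = 11))
  de_lnc <- intersect(
    res$de$gene_id[res$de$is_de],
    co$annotation$gene_id[co$annotation$biotype != "coding"])
  de_cod <- res$de[res$de$gene_id %in%
                     co$annotation$gene_id[co$annotation$biotype ==
                                             "coding"], ]
  out <- interaction_fc_contrast(res$network, de_cod, de_lnc)
  expect_lt(out$wilcoxon$p, 0.01)
  expect_lt(out$chisq$p, 0.01)
  expect_gt(out$de_fraction["interacting"], out$de_fraction["other"])
})

test_that("direction concordance is 1 for coherent shifts and high for
           planted regulators", {
  toy <- toy_network_inputs()
  net <- build_network(toy$lnc_b, toy$mrna_b, c("M1", "M2"), toy$cr)
  de <- fake_de(c("L1", "G1", "G3"), c(1, 0.5, 0.7),
                c(0.01, 0.01, 0.01))
  out <- direction_concordance(net, de, "L1")
  expect_equal(out$sign_agreement, 1)
  expect_equal(out$median_interactor_log2fc, 0.6)
  expect_error(direction_concordance(net, de, "Lx"), "unknown lncRNA")
  co <- small_cohort()
  res <- suppressMessages(run_pipeline(co, seed = 11))
  reg <- co$truth$regulators[1]
  conc <- direction_concordance(res$network, res$de, reg)
  expect_gte(conc$sign_agreement, 0.8)
})
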