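test_that("simulation spec validates its inputs", {
  expect_error(simulation_spec(n_chrom = 0), "counts")
  expect_error(simulation_spec(sigma = 0), "sigma")
  expect_error(simulation_spec(lnc_density = 1.5), "density")
  expect_error(simulation_spec(immune_shape_case = c(5, 5),
                               immune_shape_control = c(5, 5)),
               "immune mean")
  expect_error(simulation_spec(n_cerna_pairs = 10), "regulator pairs")
})

test_that("annotation placement is deterministic and respects planted
           cluster geometry", {
  spec <- small_spec()
  a1 <- simulate_annotation(spec)
  a2 <- simulate_annotation(spec)
  expect_identical(a1, a2)
  # planted cluster genes: consecutive TSS gaps below 100 kb
  layout_genes <- small_cohort()$truth$cluster_genes
  sub <- a1[a1$gene_id %in% layout_genes, ]
  expect_equal(nrow(sub), 4)
  expect_equal(unique(sub$chrom), "chr1")
  expect_true(all(diff(sort(sub$tss)) < 100e3))
  expect_error(simulate_annotation(
    simulation_spec(clusters = list(list(chrom = "chr1", span_bp = 5e3,
                                         n_genes = 5)))),
    "span too small")
})

test_that("binding tables guarantee planted shared miRNAs with dual
           evidence and honour density", {
  co <- small_cohort()
  b <- co$bindings
  hc <- high_confidence_mrna_targets(
    b$mrna[b$mrna$evidence == "experimental", ],
    b$mrna[b$mrna$evidence == "predicted", ])
  for (i in seq_len(nrow(co$truth$pairs))) {
    p <- co$truth$pairs[i, ]
    expect_true(any(b$lnc$mirna_id == p$mediator &
                      b$lnc$target_id == p$lnc_id))
    expect_true(any(hc$mirna_id == p$mediator &
                      hc$target_id == p$mrna_id))
  }
  # zero density and no planted pairs: empty tables
  null_spec <- simulation_spec(n_key_regulators = 1,
                               targets_per_regulator = 1,
                               n_cerna_pairs = 1, n_cis_pairs = 0,
                               lnc_density = 0, mrna_density = 0,
                               seed = 3)
  nb <- simulate_bindings(null_spec)
  expect_equal(nrow(nb$lnc), 1)  # only the planted pair remains
  b2 <- simulate_bindings(small_spec())
  expect_identical(nrow(b2$lnc), nrow(b$lnc))
})

test_that("uncoupled planted pairs are uncorrelated; coupled ones exceed
           the ceRNA correlation threshold", {
  spec0 <- small_spec(coupling = 0, cis_strength = 0,
                      immune_loading_frac = 0)
  co0 <- simulate_cohort(spec0)
  x0 <- log2(co0$em$values)
  p <- co0$truth$pairs[!co0$truth$pairs$is_cis, ][1:10, ]
  r0 <- vapply(seq_len(nrow(p)), function(i)
    cor(x0[p$lnc_id[i], ], x0[p$mrna_id[i], ]), numeric(1))
  expect_true(all(abs(r0) < 0.45))  # null r sd ~ 1/sqrt(n-3) at n=50
  co1 <- small_cohort()
  x1 <- log2(co1$em$values)
  p1 <- co1$truth$pairs
  r1 <- vapply(seq_len(nrow(p1)), function(i)
    cor(x1[p1$lnc_id[i], ], x1[p1$mrna_id[i], ]), numeric(1))
  expect_gte(mean(r1 > 0.5), 0.95)
})

test_that("planted group effects average to their nominal log2 value", {
  set.seed(41)
  reps <- lapply(1:5, function(i) {
    co <- simulate_cohort(small_spec(seed = 100 + i))
    x <- log2(co$em$values)
    grp <- co$em$meta$group
    tg <- co$truth$genes
    planted <- tg$gene_id[tg$beta != 0 & !tg$in_planted_cluster]
    shift <- rowMeans(x[planted, grp == "pSS"]) -
      rowMeans(x[planted, grp == "nonSS"])
    mean(shift - tg$beta[match(planted, tg$gene_id)])
  })
  expect_lt(abs(mean(unlist(reps))), 0.1)
})

test_that("the miRNA abundance table keeps mediators expressed and a
           share of the rest below the filter", {
  co <- small_cohort()
  tpm <- setNames(co$mirna_tpm$tpm, co$mirna_tpm$mirna_id)
  mediators <- unique(co$truth$pairs$mediator)
  expect_true(all(tpm[mediators] > 1))
  expect_gt(sum(tpm < 1), 0)
  expressed <- filter_expressed_mirnas(co$mirna_tpm)
  expect_true(all(mediators %in% expressed))
})

test_that("the full cohort bundle is reproducible under a fixed seed", {
  c1 <- simulate_cohort(small_spec(seed = 77))
  c2 <- simulate_cohort(small_spec(seed = 77))
  expect_identical(c1$em$values, c2$em$values)
  expect_identical(c1$annotation, c2$annotation)
  expect_identical(c1$bindings, c2$bindings)
  expect_identical(c1$mirna_tpm, c2$mirna_tpm)
  c3 <- simulate_cohort(small_spec(seed = 78))
  expect_false(identical(c1$em$values, c3$em$values))
})

test_that("immune confounding is visible before adjustment and gone
           after (the motivating property of the adjustment stage)", {
  co <- small_cohort()
  em <- log2_quantile_normalize(co$em)
  de_before <- differential_expression(em)
  de_after <- differential_expression(adjust_covariates(em))
  mk <- co$truth$markers
  expect_true(all(de_before$is_de[match(mk, de_before$gene_id)]))
  expect_false(any(de_after$is_de[match(mk, de_after$gene_id)]))
})

test_that("overexpression experiment elevates the lncRNA and its planted
           targets", {
  spec <- small_spec()
  co <- small_cohort()
  reg <- co$truth$regulators[1]
  em <- simulate_oe_experiment(spec, reg)
  x <- log2(em$values)
  oe <- em$meta$group == "OE"
  expect_gt(mean(x[reg, oe]) - mean(x[reg, !oe]), 2)
  targets <- co$truth$pairs$mrna_id[co$truth$pairs$lnc_id == reg]
  shifts <- rowMeans(x[targets, oe]) - rowMeans(x[targets, !oe])
  expect_true(all(shifts > 0.5))
})
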