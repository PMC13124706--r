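#' Run the full ceRNA inference pipeline on a cohort bundle
#'
#' Orchestrates every stage in order: normalization (log2 + quantile),
#' covariate adjustment (immune fraction + batch, group protected),
#' differential expression, genome-distribution analyses (neighbour
#' distances, clusters with permutation null, locus proximity),
#' genome-wide lncRNA x coding correlation, positivity test, ceRNA
#' network construction, regulator screens (GSEA, hypergeometric
#' enrichment, fold-change contrast), and pathway activity analyses.
#' All randomized stages derive their seeds from `seed`.
#'
#' @param cohort a bundle as returned by [simulate_cohort()] (fields:
#'   `annotation`, `bindings`, `em`, `mirna_tpm`, `pathways`, `loci`).
#' @param config an [analysis_config()].
#' @param seed master seed for the randomized stages.
#' @return list with all stage results (see details in the returned
#'   names).
#' @export
run_pipeline <- function(cohort, config = analysis_config(),
                         seed = config$rng_seed) {
  ann <- cohort$annotation
  em <- log2_quantile_normalize(cohort$em,
                                pseudocount = config$pseudocount)
  em_adj <- adjust_covariates(em)
  de <- differential_expression(em_adj, config = config)
  is_lnc <- ann$biotype %in% c("lncRNA", "novel_lncRNA")
  lnc_ids <- intersect(ann$gene_id[is_lnc], rownames(em_adj$values))
  coding_ids <- intersect(ann$gene_id[ann$biotype == "coding"],
                          rownames(em_adj$values))
  de_map <- stats::setNames(de$is_de, de$gene_id)
  # genome distribution over the expressed genes present in the matrix
  gt_expr <- ann[ann$gene_id %in% rownames(em_adj$values), , drop = FALSE]
  de_flags <- de_map[gt_expr$gene_id] %in% TRUE
  clusters <- cluster_permutation_null(
    gt_expr, de_flags, max_gap = config$nearby_kb * 1e3,
    n_perm = config$n_perm, seed = derive_seed(seed, "clusters"))
  loci_test <- locus_proximity_enrichment(
    gt_expr, de_flags, cohort$loci, window = config$nearby_kb * 1e3)
  cr <- pairwise_correlations(em_adj, lnc_ids, coding_ids,
                              config = config)
  pos_test <- positivity_test(cr)
  expressed_mir <- filter_expressed_mirnas(cohort$mirna_tpm,
                                           config$mirna_tpm_min)
  mrna_b <- cohort$bindings$mrna
  hc <- high_confidence_mrna_targets(
    mrna_b[mrna_b$evidence == "experimental", , drop = FALSE],
    mrna_b[mrna_b$evidence == "predicted", , drop = FALSE])
  net <- build_network(cohort$bindings$lnc, hc, expressed_mir, cr,
                       config = config)
  de_lnc <- intersect(de$gene_id[de$is_de], lnc_ids)
  screen <- interactor_gsea_screen(net, de[de$gene_id %in% coding_ids, ],
                                   lnc_ids = de_lnc, config = config,
                                   n_perm = config$n_perm,
                                   seed = derive_seed(seed, "gsea"))
  enrich <- interactor_de_enrichment(net,
                                     de[de$gene_id %in% coding_ids, ],
                                     universe = coding_ids,
                                     lnc_ids = de_lnc)
  psm <- score_pathways(em_adj, cohort$pathways$gs)
  dpw <- differential_pathways(psm, em_adj$meta$group,
                               fdr_max = config$pathway_fdr)
  grid <- pathway_lncrna_grid(net, cohort$pathways$gs,
                              lnc_ids = de_lnc, universe = coding_ids)
  list(em_norm = em, em_adj = em_adj, de = de, clusters = clusters,
       loci_test = loci_test, correlations = cr,
       positivity = pos_test, expressed_mirnas = expressed_mir,
       network = net, gsea_screen = screen, de_enrichment = enrich,
       pathway_scores = psm, diff_pathways = dpw, pathway_grid = grid,
       config = config, seed = seed)
}

#' One-command synthetic demo
#'
#' Simulates the default synthetic cohort, runs [run_pipeline()] and
#' writes every stage's table, plus a run manifest, into `outdir`.
#' Outputs are deterministic given `seed`: rerunning with the same seed
#' reproduces every file byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed (drives the simulation and all randomized
#'   stages).
#' @param spec optional `sim_spec` override.
#' @param config an [analysis_config()].
#' @return invisibly, the [run_pipeline()] result list with the cohort
#'   attached as `$cohort`.
#' @export
run_demo <- function(outdir, seed = 1L, spec = NULL,
                     config = analysis_config(rng_seed = seed)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) spec <- simulation_spec(seed = seed)
  cohort <- simulate_cohort(spec)
  res <- run_pipeline(cohort, config = config, seed = seed)
  res$cohort <- cohort
  fp <- function(...) file.path(outdir, ...)
  manifest <- c(sprintf("seed=%d", as.integer(seed)),
                sprintf("package_version=%s",
                        as.character(utils::packageVersion("cernet"))),
                sprintf("%s=%s", names(config),
                        vapply(config, function(v)
                          paste(format(v), collapse = ","), "")))
  writeLines(manifest, fp("manifest.txt"))
  write_gtf(cohort$annotation, fp("annotation.gtf"))
  write_expression(cohort$em, fp("expression_tpm.tsv"))
  utils::write.table(cohort$em$meta, fp("sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mirna_tpm, fp("mirna_tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_interactions(cohort$bindings$lnc, fp("bindings_lnc.tsv"))
  write_interactions(cohort$bindings$mrna, fp("bindings_mrna.tsv"))
  write_gmt(cohort$pathways$gs, fp("pathways.gmt"))
  utils::write.table(cohort$loci[c("chrom", "position")],
                     fp("loci.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_table(res$de, fp("de_genes.tsv"),
              header_lines = sprintf("fc_min=%g fdr_max=%g",
                                     attr(res$de, "fc_min"),
                                     attr(res$de, "fdr_max")))
  write_table(data.frame(null_count = res$clusters$null_counts),
              fp("cluster_null_counts.tsv"),
              header_lines = sprintf("observed=%d empirical_p=%g",
                                     res$clusters$n_clusters,
                                     res$clusters$empirical_p))
  sig <- res$correlations$pairs[res$correlations$pairs$significant, ]
  write_table(sig, fp("significant_correlations.tsv"),
              header_lines = sprintf("m_tested=%d n=%d",
                                     res$correlations$m_tested,
                                     res$correlations$n))
  write_network(res$network, fp("cerna_network.tsv"))
  write_table(res$gsea_screen, fp("regulator_gsea_screen.tsv"))
  write_table(res$de_enrichment, fp("regulator_de_enrichment.tsv"))
  write_table(res$diff_pathways, fp("differential_pathways.tsv"))
  write_table(res$pathway_grid, fp("pathway_lncrna_grid.tsv"))
  invisible(res)
}
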