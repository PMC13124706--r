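#' Analysis configuration
#'
#' Bundles every threshold used across the pipeline. Defaults follow the
#' study design the package implements: differential expression at linear
#' fold change >= 1.5 and BH-adjusted p < 0.05; genome-wide correlation
#' significance at |r| >= 0.7 with Bonferroni p < 0.05; ceRNA edges at
#' r > 0.5 (strict) with Bonferroni p < 0.05; miRNAs counted as expressed
#' above 1 TPM (strict); genomic neighbourhood windows of 100 kb ("nearby")
#' and 500 kb ("close"); 1000 permutations for the cluster null;
#' overexpression-experiment DE at fold change > 2 with FDR < 0.05 (relaxed
#' alternative FDR < 0.3); pathway calls at FDR < 0.05; regulator GSEA
#' screen significance at FDR < 0.01.
#'
#' @param de_fc_min minimum linear fold change for a DE call.
#' @param de_fdr BH FDR cutoff for a DE call.
#' @param corr_r_sig absolute Pearson r cutoff for a significant
#'   lncRNA-coding correlation.
#' @param cerna_r_min Pearson r that a ceRNA edge must strictly exceed.
#' @param mirna_tpm_min TPM that an expressed miRNA must strictly exceed.
#' @param nearby_kb,close_kb genomic distance bin edges in kilobases.
#' @param n_perm permutations for the cluster null.
#' @param oe_fc_min,oe_fdr,oe_fdr_relaxed overexpression-experiment DE
#'   thresholds.
#' @param pathway_fdr FDR cutoff for differential pathways.
#' @param pathway_fc_min fold-change threshold retained for reporting
#'   alongside pathway tests.
#' @param gsea_fdr FDR cutoff for the regulator GSEA screen.
#' @param expressed_mean_tpm mean-TPM threshold defining an expressed gene.
#' @param pseudocount added before log2 transform.
#' @param rng_seed integer seed recorded in run manifests.
#' @return A list of class `cerna_config`.
#' @export
analysis_config <- function(de_fc_min = 1.5,
                            de_fdr = 0.05,
                            corr_r_sig = 0.7,
                            cerna_r_min = 0.5,
                            mirna_tpm_min = 1.0,
                            nearby_kb = 100,
                            close_kb = 500,
                            n_perm = 1000,
                            oe_fc_min = 2.0,
                            oe_fdr = 0.05,
                            oe_fdr_relaxed = 0.3,
                            pathway_fdr = 0.05,
                            pathway_fc_min = 2.0,
                            gsea_fdr = 0.01,
                            expressed_mean_tpm = 0.1,
                            pseudocount = 1,
                            rng_seed = 1L) {
  cfg <- list(de_fc_min = de_fc_min, de_fdr = de_fdr,
              corr_r_sig = corr_r_sig, cerna_r_min = cerna_r_min,
              mirna_tpm_min = mirna_tpm_min,
              nearby_kb = nearby_kb, close_kb = close_kb,
              n_perm = as.integer(n_perm),
              oe_fc_min = oe_fc_min, oe_fdr = oe_fdr,
              oe_fdr_relaxed = oe_fdr_relaxed,
              pathway_fdr = pathway_fdr, pathway_fc_min = pathway_fc_min,
              gsea_fdr = gsea_fdr,
              expressed_mean_tpm = expressed_mean_tpm,
              pseudocount = pseudocount,
              rng_seed = as.integer(rng_seed))
  thr <- c("de_fc_min", "corr_r_sig", "cerna_r_min", "mirna_tpm_min",
           "nearby_kb", "close_kb", "oe_fc_min", "pathway_fc_min")
  for (nm in thr) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config: ", nm, " must be > 0")
  }
  for (nm in c("de_fdr", "oe_fdr", "oe_fdr_relaxed", "pathway_fdr",
               "gsea_fdr")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("config: ", nm, " must lie in (0,1)")
  }
  if (cfg$n_perm < 1) stop("config: n_perm must be >= 1")
  class(cfg) <- "cerna_config"
  cfg
}

#' @export
print.cerna_config <- function(x, ...) {
  cat("cernet analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a flat key=value config file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Unknown keys are an error. Values are coerced to the type of the
#' corresponding [analysis_config()] default.
#'
#' @param path config file path.
#' @return A `cerna_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- analysis_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("config: malformed line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("config: unknown key: ", key)
    args[[key]] <- as.numeric(val)
  }
  do.call(analysis_config, args)
}

# Stable per-stage seed derived from a single pipeline seed, so each stage is
# independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}
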