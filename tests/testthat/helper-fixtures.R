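# Shared fixtures: a scaled-down simulation spec for fast tests, tiny
# expression matrices, and a hand-built toy ceRNA setting.

small_spec <- function(seed = 11, ...) {
  simulation_spec(n_case = 30, n_control = 20, n_coding = 300,
                  n_lncrna = 80, n_mirna = 40, n_chrom = 3,
                  n_cerna_pairs = 20, n_key_regulators = 2,
                  targets_per_regulator = 8, n_cis_pairs = 4,
                  n_immune_markers = 4, n_pathways = 10,
                  pathway_size = 10,
                  clusters = list(list(chrom = "chr1", span_bp = 120e3,
                                       n_genes = 4)),
                  seed = seed, ...)
}

small_cohort_cache <- new.env()

small_cohort <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(small_cohort_cache[[key]]))
    small_cohort_cache[[key]] <- simulate_cohort(small_spec(seed))
  small_cohort_cache[[key]]
}

# a tiny expr_matrix from a plain matrix, groups split half/half
toy_em <- function(m, scale = "tpm", groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  if (is.null(groups))
    groups <- rep(c("A", "B"), length.out = ncol(m))
  meta <- data.frame(sample_id = colnames(m),
                     group = factor(groups),
                     stringsAsFactors = FALSE)
  expr_matrix(m, meta, scale = scale)
}

# hand toy for network construction: 2 lncRNAs, 3 mRNAs, 2 miRNAs
toy_network_inputs <- function(r_values = c(L1.G1 = 0.8, L1.G2 = 0.3,
                                            L1.G3 = 0.9, L2.G1 = 0.6,
                                            L2.G2 = 0.7, L2.G3 = 0.2)) {
  lnc_b <- interaction_table(
    mirna_id = c("M1", "M2"), target_id = c("L1", "L2"),
    target_kind = "lncRNA", evidence = "experimental")
  mrna_b <- interaction_table(
    mirna_id = c("M1", "M1", "M2"), target_id = c("G1", "G3", "G2"),
    target_kind = "mRNA", evidence = "experimental")
  pairs <- do.call(rbind, lapply(names(r_values), function(k) {
    ids <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(lnc_id = ids[1], coding_id = ids[2],
               r = unname(r_values[k]), stringsAsFactors = FALSE)
  }))
  n <- 126
  tstat <- pairs$r * sqrt((n - 2) / (1 - pairs$r^2))
  pairs$p <- 2 * pt(-abs(tstat), df = n - 2)
  pairs$p_bonf <- pmin(1, pairs$p * nrow(pairs))
  pairs$significant <- abs(pairs$r) >= 0.7 & pairs$p_bonf < 0.05
  cr <- list(pairs = pairs, m_tested = nrow(pairs), n = n,
             dropped = character(), alpha = 0.05, r_sig = 0.7)
  class(cr) <- "corr_result"
  list(lnc_b = lnc_b, mrna_b = mrna_b, cr = cr)
}
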