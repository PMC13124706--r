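#' Synthetic cohort specification
#'
#' Defines the generative model for a synthetic salivary-gland-style
#' case/control cohort: 92 cases vs 34 controls; 3,000 coding, 800 lncRNA
#' and 150 miRNA genes on 5 chromosomes with exponential inter-TSS gaps
#' (mean 300 kb); 3% of genes carry a planted group effect (log2
#' magnitude uniform in 0.6-1.5); immune-cell infiltration acts as a
#' confounder (Beta-distributed fraction, higher in cases, with per-gene
#' loadings and dedicated pure-immune marker genes); 200 planted
#' lncRNA-mRNA ceRNA pairs are coupled through shared latent miRNA
#' activities (coupling 1, activity sd 1, residual sd 0.3), of which
#' three lncRNAs are key regulators with 40 targets each whose mediator
#' activity shifts between groups; two genomic DE clusters are planted;
#' a shared local factor per 300-kb genomic domain creates TAD-like cis
#' co-expression between neighbouring genes.
#'
#' Expression follows the latent-activity linear model on the log2 scale:
#' `x_gs = b_g + beta_g * case_s + gamma_g * f_s - sum_k s_gk * a_ks
#'  + cis + eps_gs`, with `TPM = 2^x`. miRNA activity, not miRNA TPM,
#' drives the coupling; the miRNA TPM table is generated separately and
#' is used only for the expressed-miRNA filter.
#'
#' @param n_case,n_control sample counts.
#' @param n_coding,n_lncrna,n_mirna gene counts.
#' @param n_chrom chromosomes.
#' @param gap_mean_bp mean inter-TSS gap.
#' @param de_fraction fraction of genes given a direct group effect.
#' @param beta_range magnitude range of planted log2 group effects.
#' @param immune_shape_case,immune_shape_control Beta shapes for the
#'   immune fraction (case mean must exceed control mean).
#' @param immune_loading_frac,immune_loading_sd fraction of genes with an
#'   immune loading and its sd.
#' @param n_immune_markers,immune_marker_loading pure-immune marker genes
#'   (beta = 0, large gamma).
#' @param n_batches,batch_sd sequencing batches and per-gene batch
#'   effect sd.
#' @param coupling,activity_sd,sigma ceRNA coupling strength, latent
#'   miRNA activity sd, residual noise sd (log2 units).
#' @param n_cerna_pairs total planted ceRNA pairs (regulator pairs
#'   included).
#' @param n_key_regulators,targets_per_regulator planted key-regulator
#'   lncRNAs and their target counts.
#' @param regulator_activity_shift group shift of regulator mediator
#'   activity (negative shift raises case expression of the lncRNA and
#'   its targets).
#' @param n_cis_pairs planted ceRNA pairs whose lncRNA is placed within
#'   50 kb of its partner.
#' @param cis_strength sd of the shared per-domain local factor.
#' @param cis_domain_bp size of the TAD-like domains sharing one local
#'   factor.
#' @param lnc_density,mrna_density background binding densities per
#'   (miRNA, gene).
#' @param evidence_probs probabilities of experimental-only,
#'   predicted-only and both evidence for background mRNA edges.
#' @param mirna_low_frac fraction of non-mediator miRNAs kept below the
#'   1-TPM expression filter.
#' @param clusters list of planted DE clusters `(chrom, span_bp,
#'   n_genes)`.
#' @param cluster_beta log2 effect magnitude of cluster genes.
#' @param n_pathways,pathway_size gene-set collection emitted with the
#'   cohort; one planted set per key regulator.
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
simulation_spec <- function(n_case = 92, n_control = 34,
                            n_coding = 3000, n_lncrna = 800,
                            n_mirna = 150, n_chrom = 5,
                            gap_mean_bp = 300e3,
                            de_fraction = 0.03,
                            beta_range = c(0.6, 1.5),
                            immune_shape_case = c(12, 8),
                            immune_shape_control = c(8, 12),
                            immune_loading_frac = 0.1,
                            immune_loading_sd = 0.5,
                            n_immune_markers = 10,
                            immune_marker_loading = 5,
                            n_batches = 2, batch_sd = 0.2,
                            coupling = 1, activity_sd = 1, sigma = 0.3,
                            n_cerna_pairs = 200,
                            n_key_regulators = 3,
                            targets_per_regulator = 40,
                            regulator_activity_shift = -1.5,
                            n_cis_pairs = 30,
                            cis_strength = 0.3,
                            cis_domain_bp = 300e3,
                            lnc_density = 0.02, mrna_density = 0.02,
                            evidence_probs = c(0.35, 0.35, 0.3),
                            mirna_low_frac = 0.3,
                            clusters = list(
                              list(chrom = "chr1", span_bp = 150e3,
                                   n_genes = 5),
                              list(chrom = "chr2", span_bp = 200e3,
                                   n_genes = 5)),
                            cluster_beta = 1.5,
                            n_pathways = 50, pathway_size = 30,
                            seed = 1L) {
  spec <- as.list(environment())
  counts <- c(n_case, n_control, n_coding, n_lncrna, n_mirna, n_chrom)
  if (any(counts <= 0)) stop("simulation_spec: counts must be > 0")
  if (sigma <= 0) stop("simulation_spec: sigma must be > 0")
  if (lnc_density < 0 || lnc_density > 1 || mrna_density < 0 ||
      mrna_density > 1)
    stop("simulation_spec: density outside [0,1]")
  mu_case <- immune_shape_case[1] / sum(immune_shape_case)
  mu_ctrl <- immune_shape_control[1] / sum(immune_shape_control)
  if (mu_case <= mu_ctrl)
    stop("simulation_spec: case immune mean must exceed control mean")
  n_reg_pairs <- n_key_regulators * targets_per_regulator
  if (n_cerna_pairs < n_reg_pairs)
    stop("simulation_spec: n_cerna_pairs must cover regulator pairs")
  n_ord <- n_cerna_pairs - n_reg_pairs
  if (n_key_regulators + n_ord > n_mirna)
    stop("simulation_spec: not enough miRNAs for planted mediators")
  if (n_cis_pairs > n_ord)
    stop("simulation_spec: n_cis_pairs exceeds ordinary pairs")
  spec$n_ordinary_pairs <- n_ord
  class(spec) <- "sim_spec"
  spec
}

# id helpers
coding_ids <- function(spec) sprintf("G%04d", seq_len(spec$n_coding))
lnc_ids <- function(spec) sprintf("L%04d", seq_len(spec$n_lncrna))
mirna_ids <- function(spec) sprintf("M%04d", seq_len(spec$n_mirna))

# Deterministic planted-structure layout (no RNG): which ids are
# regulators, targets, ordinary pairs, cis pairs, markers, cluster genes.
sim_layout <- function(spec) {
  regs <- lnc_ids(spec)[seq_len(spec$n_key_regulators)]
  tpr <- spec$targets_per_regulator
  reg_targets <- split(coding_ids(spec)[seq_len(length(regs) * tpr)],
                       rep(regs, each = tpr))
  n_ord <- spec$n_ordinary_pairs
  ord_lnc <- lnc_ids(spec)[spec$n_key_regulators + seq_len(n_ord)]
  ord_mrna <- coding_ids(spec)[length(regs) * tpr + seq_len(n_ord)]
  cis_idx <- seq_len(spec$n_cis_pairs)
  n_cluster_genes <- sum(vapply(spec$clusters, `[[`, 0, "n_genes"))
  cluster_genes <- coding_ids(spec)[length(regs) * tpr + n_ord +
                                      seq_len(n_cluster_genes)]
  markers <- rev(coding_ids(spec))[seq_len(spec$n_immune_markers)]
  mediators <- c(stats::setNames(mirna_ids(spec)[seq_along(regs)], regs),
                 stats::setNames(
                   mirna_ids(spec)[length(regs) + seq_len(n_ord)],
                   ord_lnc))
  pairs <- data.frame(
    lnc_id = c(rep(regs, each = tpr), ord_lnc),
    mrna_id = c(unlist(reg_targets, use.names = FALSE), ord_mrna),
    mediator = c(rep(mediators[regs], each = tpr), mediators[ord_lnc]),
    is_regulator_pair = c(rep(TRUE, length(regs) * tpr),
                          rep(FALSE, n_ord)),
    is_cis = FALSE, stringsAsFactors = FALSE)
  pairs$is_cis[pairs$lnc_id %in% ord_lnc[cis_idx]] <- TRUE
  list(regulators = regs, reg_targets = reg_targets, pairs = pairs,
       cluster_genes = cluster_genes, markers = markers,
       mediators = mediators)
}

#' Simulate the gene annotation
#'
#' Places coding, lncRNA and miRNA genes along `n_chrom` chromosomes with
#' exponential inter-TSS gaps (mean `gap_mean_bp`). Planted cluster genes
#' are laid down with consecutive gaps below 100 kb inside the requested
#' span; cis-pair lncRNAs are placed 5-50 kb from their partner gene.
#' About 20% of lncRNAs are labelled `novel_lncRNA`.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed (default derived from `spec$seed`).
#' @return A `gene_table`.
#' @export
simulate_annotation <- function(spec,
                                seed = derive_seed(spec$seed,
                                                   "annotation")) {
  layout <- sim_layout(spec)
  for (cl in spec$clusters) {
    if (cl$span_bp < cl$n_genes * 3000)
      stop("simulate_annotation: cluster span too small for n_genes")
    if (cl$span_bp / (cl$n_genes - 1) >= 100e3)
      stop("simulate_annotation: cluster span too wide for < 100 kb gaps")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cis_lnc <- layout$pairs$lnc_id[layout$pairs$is_cis]
  cis_partner <- stats::setNames(layout$pairs$mrna_id[layout$pairs$is_cis],
                                 cis_lnc)
  scatter <- c(setdiff(coding_ids(spec), layout$cluster_genes),
               setdiff(lnc_ids(spec), cis_lnc), mirna_ids(spec))
  scatter <- sample(scatter)
  chrom_of <- sample(rep_len(sprintf("chr%d", seq_len(spec$n_chrom)),
                             length(scatter)))
  rows <- list()
  for (ch in sprintf("chr%d", seq_len(spec$n_chrom))) {
    ids <- scatter[chrom_of == ch]
    gaps <- stats::rexp(length(ids), rate = 1 / spec$gap_mean_bp)
    tss <- cumsum(1e4 + gaps)
    rows[[ch]] <- data.frame(gene_id = ids, pos = tss,
                             stringsAsFactors = FALSE)
  }
  # planted clusters appended past the scattered genes of their chromosome
  for (i in seq_along(spec$clusters)) {
    cl <- spec$clusters[[i]]
    base <- max(rows[[cl$chrom]]$pos) + 2e6
    gap <- cl$span_bp / (cl$n_genes - 1)
    offs <- cumsum(c(0, stats::runif(cl$n_genes - 1, 0.5 * gap, gap)))
    prev <- sum(vapply(spec$clusters[seq_len(i - 1)], `[[`, 0, "n_genes"))
    ids <- layout$cluster_genes[prev + seq_len(cl$n_genes)]
    rows[[cl$chrom]] <- rbind(rows[[cl$chrom]],
                              data.frame(gene_id = ids, pos = base + offs,
                                         stringsAsFactors = FALSE))
  }
  placed <- do.call(rbind, Map(function(df, ch) {
    df$chrom <- ch; df
  }, rows, names(rows)))
  # cis lncRNAs next to their partner's TSS
  partner_pos <- stats::setNames(placed$pos, placed$gene_id)
  partner_chrom <- stats::setNames(placed$chrom, placed$gene_id)
  cis_df <- data.frame(
    gene_id = cis_lnc,
    pos = partner_pos[cis_partner[cis_lnc]] +
      stats::runif(length(cis_lnc), 5e3, 50e3),
    chrom = partner_chrom[cis_partner[cis_lnc]],
    stringsAsFactors = FALSE)
  placed <- rbind(placed, cis_df)
  width <- stats::runif(nrow(placed), 2e3, 2e4)
  strand <- sample(c("+", "-"), nrow(placed), replace = TRUE)
  start <- ifelse(strand == "+", placed$pos, placed$pos - width + 1)
  biotype <- rep("coding", nrow(placed))
  is_lnc <- placed$gene_id %in% lnc_ids(spec)
  biotype[is_lnc] <- "lncRNA"
  novel <- placed$gene_id %in%
    lnc_ids(spec)[seq_len(floor(0.2 * spec$n_lncrna))]
  biotype[novel] <- "novel_lncRNA"
  biotype[placed$gene_id %in% mirna_ids(spec)] <- "miRNA"
  gt <- gene_table(placed$gene_id, biotype, placed$chrom,
                   start = round(start), end = round(start + width),
                   strand = strand)
  gt <- gt[order(gt$chrom, gt$tss), , drop = FALSE]
  rownames(gt) <- NULL
  class(gt) <- c("gene_table", "data.frame")
  gt
}

#' Simulate miRNA binding tables
#'
#' Background edges are Bernoulli per (miRNA, gene): lncRNA-side edges at
#' `lnc_density` (experimental evidence, as binding databases supply
#' them); mRNA-side edges at `mrna_density` with evidence class drawn
#' from `evidence_probs` (experimental only, predicted only, or both =
#' one row per class). Every planted ceRNA pair is guaranteed a shared
#' mediator miRNA whose mRNA edge carries both evidence classes.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed.
#' @return list with `lnc` and `mrna` `interaction_table`s.
#' @export
simulate_bindings <- function(spec,
                              seed = derive_seed(spec$seed, "bindings")) {
  layout <- sim_layout(spec)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mir <- mirna_ids(spec)
  draw_edges <- function(targets, density) {
    n <- length(mir) * length(targets)
    hit <- which(stats::runif(n) < density)
    data.frame(mirna_id = mir[(hit - 1) %% length(mir) + 1],
               target_id = targets[(hit - 1) %/% length(mir) + 1],
               stringsAsFactors = FALSE)
  }
  lnc_bg <- draw_edges(lnc_ids(spec), spec$lnc_density)
  mrna_bg <- draw_edges(coding_ids(spec), spec$mrna_density)
  ev <- sample(c("experimental", "predicted", "both"), nrow(mrna_bg),
               replace = TRUE, prob = spec$evidence_probs)
  pairs <- layout$pairs
  lnc_rows <- data.frame(mirna_id = pairs$mediator,
                         target_id = pairs$lnc_id,
                         stringsAsFactors = FALSE)
  mrna_rows <- data.frame(mirna_id = pairs$mediator,
                          target_id = pairs$mrna_id,
                          stringsAsFactors = FALSE)
  lnc_all <- rbind(lnc_bg, lnc_rows)
  lnc_tab <- interaction_table(lnc_all$mirna_id, lnc_all$target_id,
                               "lncRNA", "experimental", "sim-lnc-db")
  expand <- function(df, evidence) {
    if (!nrow(df)) return(NULL)
    data.frame(mirna_id = df$mirna_id, target_id = df$target_id,
               evidence = evidence, stringsAsFactors = FALSE)
  }
  mrna_all <- rbind(
    expand(mrna_bg[ev == "experimental", ], "experimental"),
    expand(mrna_bg[ev == "predicted", ], "predicted"),
    expand(mrna_bg[ev == "both", ], "experimental"),
    expand(mrna_bg[ev == "both", ], "predicted"),
    expand(mrna_rows, "experimental"),
    expand(mrna_rows, "predicted"))
  mrna_tab <- interaction_table(mrna_all$mirna_id, mrna_all$target_id,
                                "mRNA", mrna_all$evidence, "sim-mrna-db")
  list(lnc = lnc_tab, mrna = mrna_tab)
}

#' Simulate cohort expression and ground truth
#'
#' Draws the latent-activity linear model of [simulation_spec()]:
#' per-sample immune fractions (Beta, case mean higher), per-gene group
#' effects, immune loadings, batch offsets, shared latent miRNA
#' activities for the planted ceRNA pairs, a weak shared local factor
#' per 100-kb genomic window, and Gaussian residual noise; TPM = 2^x.
#' The miRNA TPM table keeps every planted mediator above the 1-TPM
#' expression filter and a `mirna_low_frac` share of the rest below it.
#'
#' @param spec a `sim_spec`.
#' @param annotation the `gene_table` from [simulate_annotation()].
#' @param seed RNG seed.
#' @return list: `em` (`expr_matrix`, TPM scale), `mirna_tpm`
#'   (data.frame `mirna_id`, `tpm`), `truth` (list: per-gene table,
#'   planted pair table, regulators, markers, cluster genes).
#' @export
simulate_expression <- function(spec, annotation,
                                seed = derive_seed(spec$seed,
                                                   "expression")) {
  layout <- sim_layout(spec)
  genes <- c(coding_ids(spec), lnc_ids(spec))
  if (!all(genes %in% annotation$gene_id))
    stop("simulate_expression: annotation does not cover the gene set")
  n <- spec$n_case + spec$n_control
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n))
  case <- c(rep(1, spec$n_case), rep(0, spec$n_control))
  batch <- rep_len(sprintf("b%d", seq_len(spec$n_batches)), n)
  f <- numeric(n)
  f[case == 1] <- stats::rbeta(spec$n_case, spec$immune_shape_case[1],
                               spec$immune_shape_case[2])
  f[case == 0] <- stats::rbeta(spec$n_control,
                               spec$immune_shape_control[1],
                               spec$immune_shape_control[2])
  G <- length(genes)
  is_coding <- genes %in% coding_ids(spec)
  b0 <- ifelse(is_coding, stats::rnorm(G, 4, 1.5), stats::rnorm(G, 2, 1.5))
  # immune markers: low baseline in uninfiltrated tissue, rising with
  # infiltration; also keeps them off the saturated top ranks under
  # quantile normalization
  b0[genes %in% layout$markers] <-
    stats::rnorm(spec$n_immune_markers, 1.5, 1)
  # key-regulator lncRNAs are well-expressed (detectable regulators are);
  # a low-TPM baseline would let the log2(x+1) pseudocount swallow their
  # group shift
  b0[genes %in% layout$regulators] <-
    stats::rnorm(spec$n_key_regulators, 4, 1)
  # direct group effects: planted DE genes, cluster genes, markers
  beta <- numeric(G)
  names(beta) <- genes
  excluded <- c(layout$markers, layout$regulators,
                unlist(layout$reg_targets, use.names = FALSE),
                layout$cluster_genes)
  pool <- setdiff(genes, excluded)
  n_de <- round(spec$de_fraction * G)
  de_direct <- sample(pool, n_de)
  beta[de_direct] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, spec$beta_range[1], spec$beta_range[2])
  beta[layout$cluster_genes] <-
    sample(c(-1, 1), length(layout$cluster_genes), replace = TRUE) *
    spec$cluster_beta
  gamma <- numeric(G)
  names(gamma) <- genes
  loaded <- sample(setdiff(genes, layout$markers),
                   round(spec$immune_loading_frac * G))
  gamma[loaded] <- stats::rnorm(length(loaded), 0, spec$immune_loading_sd)
  gamma[layout$markers] <- spec$immune_marker_loading
  batch_eff <- matrix(stats::rnorm(G * spec$n_batches, 0, spec$batch_sd),
                      G, spec$n_batches)
  batch_eff[, 1] <- 0
  # latent mediator activities
  mediators <- unique(layout$pairs$mediator)
  delta <- stats::setNames(rep(0, length(mediators)), mediators)
  delta[layout$mediators[layout$regulators]] <-
    spec$regulator_activity_shift
  A <- matrix(stats::rnorm(length(mediators) * n, 0, spec$activity_sd),
              length(mediators), n,
              dimnames = list(mediators, samples))
  A <- A + outer(delta[mediators], case)
  coupling_of <- matrix(0, G, length(mediators),
                        dimnames = list(genes, mediators))
  for (i in seq_len(nrow(layout$pairs))) {
    p <- layout$pairs[i, ]
    coupling_of[p$lnc_id, p$mediator] <- spec$coupling
    coupling_of[p$mrna_id, p$mediator] <- spec$coupling
  }
  x <- matrix(b0, G, n) + outer(beta, case) + outer(gamma, f) -
    coupling_of %*% A +
    batch_eff[, match(batch, sprintf("b%d", seq_len(spec$n_batches)))] +
    matrix(stats::rnorm(G * n, 0, spec$sigma), G, n)
  # shared local factor per 300-kb genomic domain (TAD-like cis
  # co-expression): all genes in a domain share one latent activity, so
  # neighbouring genes co-vary regardless of their pair distance
  if (spec$cis_strength > 0) {
    ann <- annotation[match(genes, annotation$gene_id), ]
    dom <- factor(paste(ann$chrom, ann$tss %/% spec$cis_domain_bp))
    V <- matrix(stats::rnorm(nlevels(dom) * n, 0, spec$cis_strength),
                nlevels(dom), n)
    x <- x + V[as.integer(dom), ]
  }
  dimnames(x) <- list(genes, samples)
  meta <- data.frame(sample_id = samples,
                     group = factor(ifelse(case == 1, "pSS", "nonSS"),
                                    levels = c("nonSS", "pSS")),
                     batch = batch, immune_fraction = f,
                     stringsAsFactors = FALSE)
  em <- expr_matrix(2^x, meta, scale = "tpm")
  # miRNA TPM: mediators kept expressed, a share of the rest below 1
  mir <- mirna_ids(spec)
  tpm <- 2^stats::rnorm(length(mir), 4, 1.5) + 1.01
  low <- setdiff(mir, mediators)
  low <- sample(low, round(spec$mirna_low_frac * length(low)))
  tpm[match(low, mir)] <- stats::runif(length(low), 0, 0.99)
  mirna_tpm <- data.frame(mirna_id = mir, tpm = tpm,
                          stringsAsFactors = FALSE)
  coupled_shift <- -as.vector(coupling_of %*% delta[mediators])
  truth_genes <- data.frame(
    gene_id = genes, beta = beta, gamma = gamma,
    expected_shift = beta + coupled_shift,
    is_immune_marker = genes %in% layout$markers,
    in_planted_cluster = genes %in% layout$cluster_genes,
    stringsAsFactors = FALSE)
  truth_genes$is_de_truth <- abs(truth_genes$expected_shift) >= log2(1.5)
  truth <- list(genes = truth_genes, pairs = layout$pairs,
                regulators = layout$regulators,
                reg_targets = layout$reg_targets,
                markers = layout$markers,
                cluster_genes = layout$cluster_genes)
  list(em = em, mirna_tpm = mirna_tpm, truth = truth)
}

#' Simulate planted pathway gene sets
#'
#' One planted set per key regulator (two thirds of its targets plus
#' random filler genes) and random background sets of `pathway_size`
#' coding genes.
#'
#' @param spec a `sim_spec`.
#' @param seed RNG seed.
#' @return list with `gs` (a `gene_sets`) and `planted` (names of the
#'   planted sets).
#' @export
simulate_pathways <- function(spec,
                              seed = derive_seed(spec$seed, "pathways")) {
  layout <- sim_layout(spec)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cod <- coding_ids(spec)
  quiet <- setdiff(cod, unlist(layout$reg_targets, use.names = FALSE))
  sets <- list()
  planted <- character()
  for (r in layout$regulators) {
    nm <- paste0("PLANTED_", r)
    targ <- layout$reg_targets[[r]]
    k <- ceiling(2 * spec$pathway_size / 3)
    sets[[nm]] <- c(sample(targ, min(k, length(targ))),
                    sample(quiet, spec$pathway_size - min(k, length(targ))))
    planted <- c(planted, nm)
  }
  for (i in seq_len(spec$n_pathways - length(planted))) {
    sets[[sprintf("RANDOM_%03d", i)]] <- sample(cod, spec$pathway_size)
  }
  list(gs = gene_sets(sets), planted = planted)
}

#' Simulate the full cohort bundle
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_bindings()], [simulate_expression()] and
#' [simulate_pathways()] under seeds derived from `spec$seed`, and
#' emitting GWAS-style loci at the planted cluster centres plus random
#' background positions.
#'
#' @param spec a `sim_spec`.
#' @return list: `annotation`, `bindings`, `em`, `mirna_tpm`, `truth`,
#'   `pathways`, `loci`, `spec`.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  annotation <- simulate_annotation(spec)
  bindings <- simulate_bindings(spec)
  ex <- simulate_expression(spec, annotation)
  pw <- simulate_pathways(spec)
  cl_genes <- ex$truth$cluster_genes
  ann_cl <- annotation[annotation$gene_id %in% cl_genes, ]
  centers <- stats::aggregate(tss ~ chrom, ann_cl, function(t)
    round(mean(t)))
  old <- .Random.seed_save()
  set.seed(derive_seed(spec$seed, "loci"))
  bg <- data.frame(
    chrom = sample(sprintf("chr%d", seq_len(spec$n_chrom)), 8,
                   replace = TRUE),
    pos0 = round(stats::runif(8, 1e6, 100e6)))
  .Random.seed_restore(old)
  loci <- rbind(data.frame(chrom = centers$chrom, pos0 = centers$tss),
                bg)
  loci$position <- loci$pos0 + 1
  list(annotation = annotation, bindings = bindings, em = ex$em,
       mirna_tpm = ex$mirna_tpm, truth = ex$truth, pathways = pw,
       loci = loci, spec = spec)
}

#' Simulate an overexpression experiment
#'
#' Three overexpression (OE) and three empty-vector (NC) replicates: the
#' overexpressed lncRNA is raised by `oe_log2_shift`; its planted ceRNA
#' targets respond with `target_log2_shift`; all genes get Gaussian noise
#' (sd `sigma`).
#'
#' @param spec a `sim_spec`.
#' @param lnc_id the overexpressed lncRNA.
#' @param oe_log2_shift log2 elevation of the lncRNA itself.
#' @param target_log2_shift log2 response of its planted targets.
#' @param sigma residual sd.
#' @param n_rep replicates per arm.
#' @param seed RNG seed.
#' @return An `expr_matrix` (TPM scale) with groups NC/OE.
#' @export
simulate_oe_experiment <- function(spec, lnc_id, oe_log2_shift = 3,
                                   target_log2_shift = 1.5, sigma = 0.2,
                                   n_rep = 3,
                                   seed = derive_seed(spec$seed, "oe")) {
  layout <- sim_layout(spec)
  genes <- c(coding_ids(spec), lnc_ids(spec))
  targets <- layout$pairs$mrna_id[layout$pairs$lnc_id == lnc_id]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2 * n_rep
  oe <- c(rep(0, n_rep), rep(1, n_rep))
  b0 <- stats::rnorm(length(genes), 3, 1.5)
  shift <- numeric(length(genes))
  names(shift) <- genes
  shift[lnc_id] <- oe_log2_shift
  shift[targets] <- target_log2_shift
  x <- matrix(b0, length(genes), n) + outer(shift, oe) +
    matrix(stats::rnorm(length(genes) * n, 0, sigma), length(genes), n)
  samples <- sprintf("%s%d", rep(c("NC", "OE"), each = n_rep),
                     rep(seq_len(n_rep), 2))
  dimnames(x) <- list(genes, samples)
  meta <- data.frame(sample_id = samples,
                     group = factor(ifelse(oe == 1, "OE", "NC"),
                                    levels = c("NC", "OE")),
                     stringsAsFactors = FALSE)
  expr_matrix(2^x, meta, scale = "tpm")
}
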