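#' Rank genes for preranked GSEA
#'
#' Default ranking statistic: sign(log2fc) * (-log10 p), descending, with
#' a deterministic lexicographic gene-id tie-break. Zero p-values are
#' capped at `max_score`.
#'
#' @param de a `de_result`.
#' @param metric `"signed_logp"` or `"log2fc"`.
#' @param max_score cap for -log10(p) when p underflows.
#' @return data.frame `gene_id`, `score`, sorted by decreasing score.
#' @export
rank_genes <- function(de, metric = c("signed_logp", "log2fc"),
                       max_score = 320) {
  metric <- match.arg(metric)
  score <- switch(metric,
    signed_logp = sign(de$log2fc) *
      pmin(-log10(pmax(de$p, 1e-320)), max_score),
    log2fc = de$log2fc)
  ord <- order(-score, de$gene_id)
  data.frame(gene_id = de$gene_id[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

# Weighted Kolmogorov-Smirnov-style enrichment score from hit positions.
# positions: 1-based indices of set members in the ranked list (sorted);
# weights: |score|^w at those positions; N: ranked-list length.
# Returns the signed extremum of the running sum (hit increments
# normalized to 1, miss decrement 1/(N - m)).
gsea_es <- function(positions, weights, N) {
  m <- length(positions)
  if (m == 0 || m >= N) stop("gsea_es: set empty or equal to universe")
  tot <- sum(weights)
  if (tot <= 0) weights <- rep(1, m)  # all-zero scores: unweighted
  w <- weights / sum(weights)
  d <- 1 / (N - m)
  cw <- cumsum(w)
  miss_before <- positions - seq_len(m)
  after_hit <- cw - miss_before * d
  before_hit <- c(0, cw[-m]) - miss_before * d
  hi <- max(after_hit)
  lo <- min(before_hit, 0)
  if (hi >= abs(lo)) hi else lo
}

#' Preranked gene set enrichment test
#'
#' Classic weighted running-sum GSEA on a preranked list: hit increments
#' proportional to |score|^weight (normalized to 1 over the set), miss
#' decrement 1/(N - set size); the enrichment score (ES) is the signed
#' extremum. The null is built from `n_perm` random gene sets of the same
#' size; p is the two-tailed add-one empirical probability of |ES| and
#' NES = ES / mean(|null ES| of matching sign).
#'
#' @param ranked data.frame from [rank_genes()] (`gene_id`, `score`,
#'   descending).
#' @param set character vector of member gene ids; at least 3 must be in
#'   the ranked universe, and the set must not cover it.
#' @param weight exponent on |score| for hit increments.
#' @param n_perm random sets for the null.
#' @param seed RNG seed.
#' @return list of class `gsea_result`: `es`, `nes`, `p`, `size`,
#'   `leading_edge`.
#' @export
gsea_preranked <- function(ranked, set, weight = 1, n_perm = 1000,
                           seed = 1L) {
  N <- nrow(ranked)
  pos <- sort(match(unique(set), ranked$gene_id))
  pos <- pos[!is.na(pos)]
  m <- length(pos)
  if (m < 3) stop("gsea_preranked: set too small (need >= 3 in universe)")
  if (m >= N) stop("gsea_preranked: set covers the ranked universe")
  absw <- abs(ranked$score)^weight
  es <- gsea_es(pos, absw[pos], N)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    rp <- sort(sample.int(N, m))
    gsea_es(rp, absw[rp], N)
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  # leading edge: members at or before the ES extremum
  cw <- cumsum(absw[pos] / max(sum(absw[pos]), .Machine$double.eps))
  d <- 1 / (N - m)
  running_after <- cw - (pos - seq_len(m)) * d
  peak <- if (es >= 0) which.max(running_after) else which.min(
    c(0, cw[-m]) - (pos - seq_len(m)) * d)
  leading <- if (es >= 0) ranked$gene_id[pos[seq_len(peak)]]
             else ranked$gene_id[pos[pos >= pos[peak]]]
  res <- list(es = es, nes = nes, p = p, size = m,
              leading_edge = leading)
  class(res) <- "gsea_result"
  res
}

#' GSEA screen of lncRNA interactor sets
#'
#' Runs one preranked GSEA per candidate lncRNA, using its ceRNA-network
#' interactor set against the ranked coding-gene DE statistic, and
#' BH-adjusts across lncRNAs. lncRNAs with fewer than 3 ranked
#' interactors are skipped with a message. A positive NES means the
#' interactors are coordinately shifted toward the case group.
#'
#' @param net a `cerna_network`.
#' @param de a `de_result` on the coding universe.
#' @param lnc_ids candidate lncRNAs (typically the DE lncRNAs present in
#'   the network); defaults to all network lncRNAs.
#' @param config an [analysis_config()]; supplies `gsea_fdr`.
#' @param weight,n_perm,seed passed to [gsea_preranked()].
#' @return data.frame: `lnc_id`, `n_interactors`, `es`, `nes`, `p`,
#'   `fdr`, `significant`, sorted by increasing p then decreasing |nes|.
#' @export
interactor_gsea_screen <- function(net, de, lnc_ids = NULL,
                                   config = analysis_config(),
                                   weight = 1, n_perm = 1000, seed = 1L) {
  sets <- interactors_by_lncrna(net)
  if (!is.null(lnc_ids)) sets <- sets[intersect(lnc_ids, names(sets))]
  ranked <- rank_genes(de)
  keep <- vapply(sets, function(s)
    sum(unique(s) %in% ranked$gene_id) >= 3, TRUE)
  if (any(!keep))
    message("interactor_gsea_screen: skipped ", sum(!keep),
            " lncRNAs with < 3 ranked interactors")
  sets <- sets[keep]
  if (!length(sets))
    return(data.frame(lnc_id = character(), n_interactors = integer(),
                      es = numeric(), nes = numeric(), p = numeric(),
                      fdr = numeric(), significant = logical()))
  rows <- lapply(seq_along(sets), function(i) {
    g <- gsea_preranked(ranked, sets[[i]], weight = weight,
                        n_perm = n_perm,
                        seed = derive_seed(seed, names(sets)[i]))
    data.frame(lnc_id = names(sets)[i], n_interactors = g$size,
               es = g$es, nes = g$nes, p = g$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$significant <- out$fdr < config$gsea_fdr
  out <- out[order(out$p, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric DE enrichment of each lncRNA's interactors
#'
#' Upper-tail hypergeometric test of the DE count among each lncRNA's
#' coding interactors against the expressed coding universe, BH-adjusted
#' across lncRNAs, with star levels at FDR 0.05 / 0.01 / 0.001.
#'
#' @param net a `cerna_network`.
#' @param de a `de_result` on the coding universe.
#' @param universe coding gene universe (default: DE table genes).
#' @param lnc_ids candidate lncRNAs; defaults to all network lncRNAs.
#' @return data.frame: `lnc_id`, `n_interactors`, `n_de_interactors`,
#'   `p`, `fdr`, `stars`.
#' @export
interactor_de_enrichment <- function(net, de, universe = de$gene_id,
                                     lnc_ids = NULL) {
  sets <- interactors_by_lncrna(net)
  if (!is.null(lnc_ids)) sets <- sets[intersect(lnc_ids, names(sets))]
  de_set <- de$gene_id[de$is_de]
  special <- sum(universe %in% de_set)
  rows <- lapply(names(sets), function(lnc) {
    inter <- intersect(unique(sets[[lnc]]), universe)
    if (!length(inter)) return(NULL)
    k <- sum(inter %in% de_set)
    ht <- hypergeom_enrichment(k, length(inter), special,
                               length(universe))
    data.frame(lnc_id = lnc, n_interactors = length(inter),
               n_de_interactors = k, p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lnc_id = character(), n_interactors = integer(),
                      n_de_interactors = integer(), p = numeric(),
                      fdr = numeric(), stars = character()))
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$stars <- cut(out$fdr, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast of expression change between interactors and non-interactors
#'
#' Splits the coding universe into genes interacting with at least one DE
#' lncRNA and the rest, then (i) compares |log2fc| by Wilcoxon (greater)
#' and (ii) compares DE proportions by chi-square.
#'
#' @param net a `cerna_network`.
#' @param de a `de_result` on the coding universe.
#' @param de_lnc_ids DE lncRNA ids.
#' @return list with `wilcoxon` and `chisq` (`cerna_test`s) and the
#'   interactor flag vector.
#' @export
interaction_fc_contrast <- function(net, de, de_lnc_ids) {
  inter_genes <- unique(net$edges$mrna_id[net$edges$lnc_id %in% de_lnc_ids])
  flag <- de$gene_id %in% inter_genes
  if (!any(flag)) stop("interaction_fc_contrast: empty interactor group")
  if (all(flag)) stop("interaction_fc_contrast: empty complement")
  w <- wilcoxon_rank_sum(abs(de$log2fc[flag]), abs(de$log2fc[!flag]),
                         "greater")
  tab <- rbind(interacting = c(sum(de$is_de[flag]), sum(!de$is_de[flag])),
               other = c(sum(de$is_de[!flag]), sum(!de$is_de[!flag])))
  list(wilcoxon = w, chisq = chisq_2xk(tab), interactor = flag,
       de_fraction = c(interacting = mean(de$is_de[flag]),
                       other = mean(de$is_de[!flag])))
}

#' Direction concordance between a lncRNA and its interactors
#'
#' @param net a `cerna_network`.
#' @param de a `de_result` covering the lncRNA and its interactors.
#' @param lnc_id one lncRNA id present in the network.
#' @return list: `median_interactor_log2fc`, `sign_agreement` (fraction
#'   of interactors whose log2fc sign matches the lncRNA's),
#'   `interactor_log2fc`.
#' @export
direction_concordance <- function(net, de, lnc_id) {
  inter <- interactors_by_lncrna(net)[[lnc_id]]
  if (is.null(inter)) stop("direction_concordance: unknown lncRNA ",
                           lnc_id)
  lfc_lnc <- de$log2fc[match(lnc_id, de$gene_id)]
  if (is.na(lfc_lnc)) stop("direction_concordance: lncRNA not in DE table")
  lfc <- de$log2fc[match(intersect(inter, de$gene_id), de$gene_id)]
  list(median_interactor_log2fc = stats::median(lfc),
       sign_agreement = mean(sign(lfc) == sign(lfc_lnc)),
       interactor_log2fc = lfc)
}
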