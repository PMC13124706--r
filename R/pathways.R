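# Per-sample rank-based set score: the integrated difference between the
# weighted ECDF of in-set genes and the ECDF of out-set genes along the
# sample's expression ranking. The raw statistic is centred at its value
# for an evenly interleaved set (the rank-weighting gives the in-set ECDF
# a nonzero expectation under uniformity) and scaled piecewise so that a
# set occupying the top ranks scores +1, the bottom ranks -1, and an
# evenly spread set 0. Depends on ranks only, so it is invariant to
# monotone per-sample transforms.
sample_set_score <- function(ord_ids, set_idx_in_order, N, tau = 0.25) {
  m <- length(set_idx_in_order)
  raw <- function(pos) {
    w <- (N - pos + 1)^tau
    # sum over list positions i of P_in(i): each hit j contributes w_j
    # for every i >= p_j
    s_in <- sum(w * (N - pos + 1)) / sum(w)
    all_pos <- N * (N + 1) / 2
    s_out <- (all_pos - sum(N - pos + 1)) / (N - m)
    s_in - s_out
  }
  stat <- raw(set_idx_in_order)
  ref <- raw(pmax(1, pmin(N, round((seq_len(m) - 0.5) * N / m))))
  hi <- raw(seq_len(m)) - ref
  lo <- raw((N - m + 1):N) - ref
  centered <- stat - ref
  if (centered >= 0) centered / hi else centered / abs(lo)
}

#' Single-sample pathway activity scores
#'
#' For each sample, genes are ranked by expression (descending) and each
#' gene set receives a rank-based running-sum score: the normalized
#' integrated difference between the weighted (exponent 0.25) ECDF of
#' in-set genes and the ECDF of out-set genes, scaled to [-1, 1] by the
#' maximum attainable deviation. Positive scores mean the set sits high
#' in that sample's expression ranking. This rank statistic is a
#' documented single-sample surrogate for kernel-based set variation
#' scoring: downstream stages need only a per-sample set score with
#' monotone behaviour, and the rank construction makes the score
#' invariant to monotone per-sample transforms.
#'
#' @param em an `expr_matrix` on a normalized scale.
#' @param gs a `gene_sets` collection; sets with fewer than 3 members in
#'   the matrix are dropped with a message.
#' @param tau rank-weight exponent.
#' @return list of class `pathway_scores`: `scores`
#'   (pathway x sample matrix), `set_sizes`, `method`.
#' @export
score_pathways <- function(em, gs, tau = 0.25) {
  genes <- rownames(em$values)
  N <- length(genes)
  sets_idx <- lapply(gs$sets, function(s) {
    idx <- match(unique(s), genes)
    idx[!is.na(idx)]
  })
  keep <- lengths(sets_idx) >= 3
  if (any(lengths(sets_idx) >= N))
    stop("score_pathways: a set covers the whole universe")
  if (any(!keep))
    message("score_pathways: dropped ", sum(!keep),
            " sets with < 3 resolved members")
  sets_idx <- sets_idx[keep]
  if (!length(sets_idx)) stop("score_pathways: no usable gene sets")
  scores <- matrix(NA_real_, length(sets_idx), ncol(em$values),
                   dimnames = list(names(sets_idx), colnames(em$values)))
  for (j in seq_len(ncol(em$values))) {
    ord <- order(-em$values[, j])
    pos_of_gene <- integer(N)
    pos_of_gene[ord] <- seq_len(N)
    for (i in seq_along(sets_idx)) {
      scores[i, j] <- sample_set_score(ord,
                                       sort(pos_of_gene[sets_idx[[i]]]),
                                       N, tau)
    }
  }
  res <- list(scores = scores, set_sizes = lengths(sets_idx),
              method = sprintf("rank running-sum set score, tau=%g", tau))
  class(res) <- "pathway_scores"
  res
}

#' Differential pathway activity between groups
#'
#' Per-pathway two-group test on the activity scores (Wilcoxon rank-sum
#' by default, Student's t available), BH correction, and the score
#' difference (case minus control means) as the effect.
#'
#' @param psm a `pathway_scores` object.
#' @param groups factor of length `ncol(scores)` with two levels
#'   (control level first).
#' @param test `"wilcoxon"` or `"t"`.
#' @param fdr_max significance cutoff on the BH-adjusted p.
#' @return data.frame: `pathway`, `score_diff`, `p`, `fdr`,
#'   `significant`.
#' @export
differential_pathways <- function(psm, groups, test = c("wilcoxon", "t"),
                                  fdr_max = 0.05) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("differential_pathways: need two groups")
  if (min(table(groups)) < 3)
    stop("differential_pathways: need >= 3 samples per group")
  lev <- levels(groups)
  a <- psm$scores[, groups == lev[2], drop = FALSE]
  b <- psm$scores[, groups == lev[1], drop = FALSE]
  p <- vapply(seq_len(nrow(psm$scores)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (test == "wilcoxon") wilcoxon_rank_sum(x, y)$p
    else if (stats::sd(x) == 0 && stats::sd(y) == 0) 1
    else stats::t.test(x, y)$p.value
  }, numeric(1))
  out <- data.frame(pathway = rownames(psm$scores),
                    score_diff = rowMeans(a) - rowMeans(b),
                    p = p, stringsAsFactors = FALSE)
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$significant <- out$fdr < fdr_max
  rownames(out) <- NULL
  out
}

#' Hypergeometric DE enrichment per pathway
#'
#' Pathways with fewer than `min_de` DE members are excluded before
#' testing; the rest get an upper-tail hypergeometric p, BH correction
#' and star levels.
#'
#' @param gs a `gene_sets` collection.
#' @param de a `de_result` on the universe.
#' @param universe gene universe (default: DE table genes).
#' @param min_de minimum DE members for a pathway to be tested.
#' @return data.frame: `pathway`, `size`, `n_de`, `p`, `fdr`, `stars`.
#' @export
pathway_de_enrichment <- function(gs, de, universe = de$gene_id,
                                  min_de = 3) {
  de_set <- de$gene_id[de$is_de]
  special <- sum(universe %in% de_set)
  rows <- lapply(names(gs$sets), function(nm) {
    members <- intersect(unique(gs$sets[[nm]]), universe)
    k <- sum(members %in% de_set)
    if (k < min_de || !length(members)) return(NULL)
    ht <- hypergeom_enrichment(k, length(members), special,
                               length(universe))
    data.frame(pathway = nm, size = length(members), n_de = k, p = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway = character(), size = integer(),
                      n_de = integer(), p = numeric(), fdr = numeric(),
                      stars = character()))
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$stars <- cut(out$fdr, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' lncRNA-by-pathway interactor enrichment grid
#'
#' For every (lncRNA, pathway) cell: 2x2 of pathway membership against
#' lncRNA interactorship over the expressed coding universe, upper-tail
#' hypergeometric p, cross-product odds ratio, and BH correction over the
#' whole grid. Cells with an empty interactor or member set are skipped.
#'
#' @param net a `cerna_network`.
#' @param gs a `gene_sets` collection.
#' @param lnc_ids lncRNAs to test (default: all network lncRNAs).
#' @param universe expressed coding universe.
#' @return long-format data.frame: `lnc_id`, `pathway`, `overlap`,
#'   `odds_ratio`, `p`, `fdr`, `significant`.
#' @export
pathway_lncrna_grid <- function(net, gs, lnc_ids = NULL, universe) {
  sets <- interactors_by_lncrna(net)
  if (!is.null(lnc_ids)) sets <- sets[intersect(lnc_ids, names(sets))]
  rows <- list()
  for (lnc in names(sets)) {
    inter <- intersect(unique(sets[[lnc]]), universe)
    if (!length(inter)) next
    for (nm in names(gs$sets)) {
      members <- intersect(unique(gs$sets[[nm]]), universe)
      if (!length(members)) next
      k <- length(intersect(inter, members))
      ht <- hypergeom_enrichment(k, length(inter), length(members),
                                 length(universe))
      a <- k
      b <- length(inter) - k
      cc <- length(members) - k
      d <- length(universe) - length(inter) - cc
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_id = lnc, pathway = nm, overlap = k,
        odds_ratio = (a * d) / (b * cc), p = ht$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(lnc_id = character(), pathway = character(),
                      overlap = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  out$fdr <- adjust_pvalues(out$p, "bh")
  out$significant <- out$fdr < 0.05
  rownames(out) <- NULL
  out
}

#' Within-pathway contrast of interacting vs non-interacting members
#'
#' For each pathway, Wilcoxon (two-sided) on log2fc between member genes
#' interacting with at least one DE lncRNA and the remaining members,
#' plus the fraction of the pathway's DE genes that are interactors.
#' Pathways whose members fall entirely on one side are skipped with a
#' message.
#'
#' @param net a `cerna_network`.
#' @param gs a `gene_sets` collection.
#' @param de a `de_result` on the coding universe.
#' @param de_lnc_ids DE lncRNA ids.
#' @return data.frame: `pathway`, `n_interacting`, `n_other`, `p`,
#'   `de_interactor_fraction`.
#' @export
member_fc_contrast <- function(net, gs, de, de_lnc_ids) {
  inter_genes <- unique(net$edges$mrna_id[net$edges$lnc_id %in% de_lnc_ids])
  skipped <- 0L
  rows <- lapply(names(gs$sets), function(nm) {
    members <- intersect(unique(gs$sets[[nm]]), de$gene_id)
    flag <- members %in% inter_genes
    if (!any(flag) || all(flag)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    lfc <- de$log2fc[match(members, de$gene_id)]
    is_de <- de$is_de[match(members, de$gene_id)]
    frac <- if (sum(is_de)) sum(is_de & flag) / sum(is_de) else NA_real_
    data.frame(pathway = nm, n_interacting = sum(flag),
               n_other = sum(!flag),
               p = wilcoxon_rank_sum(lfc[flag], lfc[!flag])$p,
               de_interactor_fraction = frac, stringsAsFactors = FALSE)
  })
  if (skipped)
    message("member_fc_contrast: skipped ", skipped,
            " one-sided pathways")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), n_interacting = integer(),
                      n_other = integer(), p = numeric(),
                      de_interactor_fraction = numeric())
  rownames(out) <- NULL
  out
}
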