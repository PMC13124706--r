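#' Differential expression for an overexpression experiment
#'
#' Same linear-model engine as [differential_expression()], at the
#' overexpression-experiment thresholds (fold change > `oe_fc_min`,
#' FDR < `oe_fdr`), with a relaxed-FDR mode for weak perturbations.
#'
#' @param em an `expr_matrix` of the OE/NC arms (log-scale normalized),
#'   metadata `group` with the control level first (e.g. NC, OE).
#' @param config an [analysis_config()].
#' @param relaxed use `oe_fdr_relaxed` instead of `oe_fdr`.
#' @return A `de_result`.
#' @export
oe_differential_expression <- function(em, config = analysis_config(),
                                       relaxed = FALSE) {
  fdr <- if (relaxed) config$oe_fdr_relaxed else config$oe_fdr
  differential_expression(em, covariates = character(), config = config,
                          fc_min = config$oe_fc_min, fdr_max = fdr)
}

#' DEG overlap between two experiments
#'
#' 2x2 of DE-in-A against DE-in-B over a shared universe, one-sided
#' (greater) Fisher's exact test, cross-product odds ratio. Strata:
#' `"ALL"` ignores direction; `"UP"`/`"DOWN"` require the matching sign
#' in both experiments for a gene to count as DE.
#'
#' @param deA,deB `de_result`s covering `universe`.
#' @param universe shared gene universe.
#' @param stratum `"ALL"`, `"UP"` or `"DOWN"`.
#' @return list of class `overlap_result`: `table`, `odds_ratio`, `p`,
#'   `stratum`, `overlap`, `n_deA`, `n_deB`.
#' @export
deg_overlap <- function(deA, deB, universe,
                        stratum = c("ALL", "UP", "DOWN")) {
  stratum <- match.arg(stratum)
  if (!all(universe %in% deA$gene_id) || !all(universe %in% deB$gene_id))
    stop("deg_overlap: universe mismatch")
  pick <- function(de) {
    i <- match(universe, de$gene_id)
    flag <- de$is_de[i]
    if (stratum == "UP") flag <- flag & de$log2fc[i] > 0
    if (stratum == "DOWN") flag <- flag & de$log2fc[i] < 0
    flag
  }
  a <- pick(deA); b <- pick(deB)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE)
  ft <- fisher_exact(tab, "greater")
  res <- list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
              stratum = stratum, overlap = tab[1, 1], n_deA = sum(a),
              n_deB = sum(b))
  class(res) <- "overlap_result"
  res
}

#' Do a lncRNA's network interactors respond to its overexpression?
#'
#' Wilcoxon (greater) on -log10 p of the OE-vs-NC test between the
#' lncRNA's ceRNA interactors and all other genes, plus the DEG
#' proportions of both groups compared by chi-square.
#'
#' @param net a `cerna_network`.
#' @param lnc_id the overexpressed lncRNA (must be in the network).
#' @param de_oe `de_result` of the OE experiment.
#' @return list with `wilcoxon`, `chisq`, `de_fraction` (interactors,
#'   others).
#' @export
interactor_response_test <- function(net, lnc_id, de_oe) {
  inter <- interactors_by_lncrna(net)[[lnc_id]]
  if (is.null(inter))
    stop("interactor_response_test: lncRNA absent from network")
  flag <- de_oe$gene_id %in% inter
  flag[de_oe$gene_id == lnc_id] <- NA  # the perturbed gene itself
  keep <- !is.na(flag)
  if (!any(flag[keep])) stop("interactor_response_test: zero interactors")
  score <- -log10(pmax(de_oe$p, 1e-320))
  w <- wilcoxon_rank_sum(score[keep & flag %in% TRUE],
                         score[keep & flag %in% FALSE], "greater")
  tab <- rbind(
    interacting = c(sum(de_oe$is_de[keep & flag %in% TRUE]),
                    sum(!de_oe$is_de[keep & flag %in% TRUE])),
    other = c(sum(de_oe$is_de[keep & flag %in% FALSE]),
              sum(!de_oe$is_de[keep & flag %in% FALSE])))
  list(wilcoxon = w, chisq = chisq_2xk(tab),
       de_fraction = c(interacting = unname(tab[1, 1] / sum(tab[1, ])),
                       other = unname(tab[2, 1] / sum(tab[2, ]))))
}

#' Clinical-feature association report
#'
#' Binary features are given as positive/assessed counts per group and
#' tested by two-sided Fisher's exact test (minimum-likelihood rule);
#' continuous features as per-subject values and tested by Wilcoxon.
#' Percentages are rounded half-up to integers for display.
#'
#' @param binary data.frame with columns `feature`, `case_pos`,
#'   `case_n`, `control_pos`, `control_n` (assessed counts), or `NULL`.
#' @param continuous named list of lists with `case` and `control`
#'   numeric vectors, or `NULL`.
#' @return data.frame: `feature`, `case_display`, `control_display`,
#'   `p`, `test`.
#' @export
clinical_association <- function(binary = NULL, continuous = NULL) {
  rows <- list()
  if (!is.null(binary)) {
    for (i in seq_len(nrow(binary))) {
      b <- binary[i, ]
      if (b$case_n == 0 || b$control_n == 0)
        stop("clinical_association: feature with zero assessed subjects: ",
             b$feature)
      tab <- matrix(c(b$case_pos, b$case_n - b$case_pos,
                      b$control_pos, b$control_n - b$control_pos),
                    2, 2, byrow = TRUE)
      ft <- fisher_exact(tab, "two_sided")
      rows[[length(rows) + 1L]] <- data.frame(
        feature = b$feature,
        case_display = sprintf("%d/%d(%d%%)", b$case_pos, b$case_n,
                               round_half_up(100 * b$case_pos / b$case_n)),
        control_display = sprintf("%d/%d(%d%%)", b$control_pos,
                                  b$control_n,
                                  round_half_up(100 * b$control_pos /
                                                  b$control_n)),
        p = ft$p, test = "fisher_two_sided", stringsAsFactors = FALSE)
    }
  }
  for (nm in names(continuous)) {
    v <- continuous[[nm]]
    w <- wilcoxon_rank_sum(v$case, v$control)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, case_display = sprintf("%.2f", mean(v$case)),
      control_display = sprintf("%.2f", mean(v$control)),
      p = w$p, test = "wilcoxon", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Expression vs binary clinical feature
#'
#' Wilcoxon rank-sum on a gene's normalized expression between
#' feature-positive and feature-negative samples.
#'
#' @param em an `expr_matrix` on a log scale.
#' @param gene_id one gene.
#' @param feature logical vector along samples.
#' @return A `cerna_test`.
#' @export
expression_vs_feature <- function(em, gene_id, feature) {
  if (!gene_id %in% rownames(em$values))
    stop("expression_vs_feature: unknown gene ", gene_id)
  if (all(feature) || !any(feature))
    stop("expression_vs_feature: a feature stratum is empty")
  x <- em$values[gene_id, ]
  wilcoxon_rank_sum(x[feature], x[!feature])
}
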