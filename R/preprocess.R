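#' Log2 transform and quantile normalization
#'
#' Applies `log2(x + pseudocount)` and then maps each column's ranks onto
#' the vector of cross-column rank means (the reference distribution), so
#' that all columns share an identical value multiset afterwards. Tied
#' values receive the mean of their tied ranks' reference values. The
#' operation is idempotent on its own output.
#'
#' @param em an `expr_matrix` on the `tpm` scale (or `log2` when
#'   `log_transform = FALSE` has already been applied upstream).
#' @param pseudocount added before the log2 transform.
#' @param log_transform set `FALSE` to quantile-normalize values already
#'   on the log scale.
#' @return An `expr_matrix` on the `log2_quantile` scale.
#' @export
log2_quantile_normalize <- function(em, pseudocount = 1,
                                    log_transform = TRUE) {
  if (log_transform) {
    em <- advance_scale(em, "tpm", "log2")
    em$values <- log2(em$values + pseudocount)
  }
  em <- advance_scale(em, "log2", "log2_quantile")
  em$values <- quantile_normalize(em$values)
  em
}

# Rank-mean quantile normalization with average-rank tie handling.
quantile_normalize <- function(m) {
  n <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort, method = "radix"))
  out <- apply(m, 2, function(col) {
    if (length(unique(col)) == 1L) {
      message("quantile_normalize: constant column mapped to reference mean")
      return(rep(mean(ref), n))
    }
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Remove nuisance covariate effects while protecting the group contrast
#'
#' Per gene, fits least squares on the protected design (group) plus the
#' nuisance covariates (immune fraction, batch) and subtracts only the
#' fitted nuisance contribution, leaving the intercept and group effect in
#' place. Delegates to `limma::removeBatchEffect`.
#'
#' @param em an `expr_matrix` on the `log2_quantile` scale.
#' @param nuisance character vector naming metadata columns to remove;
#'   factor-like columns are treated as batches, numeric ones as
#'   covariates.
#' @param protect metadata column whose effect must be preserved
#'   (default `"group"`).
#' @return An `expr_matrix` on the `adjusted` scale.
#' @export
adjust_covariates <- function(em, nuisance = c("immune_fraction", "batch"),
                              protect = "group") {
  nuisance <- intersect(nuisance, names(em$meta))
  if (!length(nuisance)) stop("adjust_covariates: no nuisance columns found")
  design <- stats::model.matrix(
    stats::reformulate(protect), data = em$meta)
  batches <- list()
  covars <- NULL
  for (nm in nuisance) {
    v <- em$meta[[nm]]
    if (is.numeric(v)) covars <- cbind(covars, v)
    else batches[[length(batches) + 1L]] <- as.factor(v)
  }
  args <- list(x = em$values, covariates = covars, design = design)
  if (length(batches) >= 1) args$batch <- batches[[1]]
  if (length(batches) >= 2) args$batch2 <- batches[[2]]
  qrd <- qr(cbind(design, covars,
                  if (length(batches))
                    do.call(cbind, lapply(batches, function(b)
                      stats::model.matrix(~b)[, -1, drop = FALSE]))))
  if (qrd$rank < ncol(qrd$qr)) stop("adjust_covariates: rank-deficient design")
  adj <- do.call(limma::removeBatchEffect, args)
  em <- advance_scale(em, "log2_quantile", "adjusted")
  em$values <- adj
  em
}

#' Per-gene linear-model differential expression
#'
#' Ordinary least squares of each gene's (adjusted log2) expression on the
#' group contrast plus optional covariates, with a classical two-sided
#' t-test on the group coefficient and BH correction across genes. The
#' log2 fold change is the group-coefficient estimate. A gene is flagged
#' DE when its linear fold change `2^|log2fc|` is at least `fc_min` and
#' its FDR is below `fdr_max`. This linear-model route on normalized
#' abundances is a deliberate, documented stand-in for count-based
#' negative-binomial modelling: downstream stages consume only
#' (log2fc, fdr, is_de).
#'
#' @param em an `expr_matrix` on the `log2_quantile` or `adjusted` scale.
#' @param covariates metadata columns to include in the design (those
#'   present are used; default `"batch"`).
#' @param config an [analysis_config()].
#' @param fc_min,fdr_max override the config thresholds.
#' @return data.frame of class `de_result`: `gene_id`, `mean_case`,
#'   `mean_control`, `log2fc`, `p`, `fdr`, `is_de`, with the thresholds
#'   and method in attributes.
#' @export
differential_expression <- function(em, covariates = "batch",
                                    config = analysis_config(),
                                    fc_min = config$de_fc_min,
                                    fdr_max = config$de_fdr) {
  if (!em$scale %in% c("log2_quantile", "adjusted"))
    stop("differential_expression: expected log-scale normalized values")
  grp <- em$meta$group
  if (nlevels(grp) != 2) stop("differential_expression: need two groups")
  if (min(table(grp)) < 3)
    stop("differential_expression: need >= 3 samples per group")
  covariates <- intersect(covariates, names(em$meta))
  covariates <- covariates[vapply(covariates, function(nm)
    length(unique(em$meta[[nm]])) > 1, TRUE)]
  form <- if (length(covariates))
    stats::reformulate(c("group", covariates))
  else ~group
  design <- stats::model.matrix(form, data = em$meta)
  fit <- limma::lmFit(em$values, design)
  if (any(fit$df.residual <= 0))
    stop("differential_expression: zero residual degrees of freedom")
  coef_idx <- 2L  # group contrast: second level vs first
  log2fc <- fit$coefficients[, coef_idx]
  tstat <- log2fc / (fit$stdev.unscaled[, coef_idx] * fit$sigma)
  p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  fdr <- adjust_pvalues(p, "bh")
  lev <- levels(grp)
  res <- data.frame(
    gene_id = rownames(em$values),
    mean_case = rowMeans(em$values[, grp == lev[2], drop = FALSE]),
    mean_control = rowMeans(em$values[, grp == lev[1], drop = FALSE]),
    log2fc = log2fc, p = p, fdr = fdr,
    is_de = (2^abs(log2fc) >= fc_min) & (fdr < fdr_max),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "fc_min") <- fc_min
  attr(res, "fdr_max") <- fdr_max
  attr(res, "method") <- "OLS t-test on normalized log2 abundance"
  attr(res, "case_level") <- lev[2]
  class(res) <- c("de_result", "data.frame")
  res
}
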