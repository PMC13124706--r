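#' Expressed miRNA filter
#'
#' Keeps miRNAs whose TPM strictly exceeds `min_tpm`.
#'
#' @param mirna_tpm named numeric vector (or data.frame with `mirna_id`
#'   and `tpm`) of miRNA abundances.
#' @param min_tpm strict TPM threshold.
#' @return character vector of expressed miRNA ids.
#' @export
filter_expressed_mirnas <- function(mirna_tpm, min_tpm = 1.0) {
  if (is.data.frame(mirna_tpm))
    mirna_tpm <- stats::setNames(mirna_tpm$tpm, mirna_tpm$mirna_id)
  if (!length(mirna_tpm)) stop("filter_expressed_mirnas: empty table")
  keep <- names(mirna_tpm)[mirna_tpm > min_tpm]
  if (!length(keep))
    warning("filter_expressed_mirnas: no miRNA above ", min_tpm, " TPM")
  keep
}

#' High-confidence miRNA-mRNA targets
#'
#' Intersects experimentally supported and computationally predicted
#' miRNA-mRNA edges on (mirna_id, target_id); the retained edges carry
#' both contributing source strings.
#'
#' @param experimental,predicted `interaction_table`s (mRNA side).
#' @return An `interaction_table` with `evidence = "experimental"` rows
#'   restricted to pairs present in both inputs.
#' @export
high_confidence_mrna_targets <- function(experimental, predicted) {
  key <- function(it) paste(it$mirna_id, it$target_id, sep = "\r")
  keep <- key(experimental) %in% key(predicted)
  hc <- experimental[keep, , drop = FALSE]
  if (nrow(hc)) {
    pred_src <- stats::setNames(predicted$source, key(predicted))
    hc$source <- paste(hc$source, pred_src[key(hc)], sep = "+")
  }
  rownames(hc) <- NULL
  class(hc) <- c("interaction_table", "data.frame")
  hc
}

new_cerna_network <- function(edges, r_min, alpha, m_tested) {
  if (!nrow(edges)) {
    nodes <- data.frame(node_id = character(), class = character(),
                        degree = integer(), stringsAsFactors = FALSE)
    net <- list(edges = edges, nodes = nodes, r_min = r_min,
                alpha = alpha, m_tested = m_tested)
    class(net) <- "cerna_network"
    return(net)
  }
  nodes <- data.frame(
    node_id = c(unique(edges$lnc_id), unique(edges$mrna_id)),
    class = rep(c("lncRNA", "mRNA"),
                c(length(unique(edges$lnc_id)),
                  length(unique(edges$mrna_id)))),
    stringsAsFactors = FALSE)
  deg <- c(table(edges$lnc_id)[nodes$node_id[nodes$class == "lncRNA"]],
           table(edges$mrna_id)[nodes$node_id[nodes$class == "mRNA"]])
  nodes$degree <- as.integer(deg)
  net <- list(edges = edges, nodes = nodes, r_min = r_min, alpha = alpha,
              m_tested = m_tested)
  class(net) <- "cerna_network"
  net
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d edges, %d lncRNAs, %d mRNAs (r > %g)\n",
              nrow(x$edges), sum(x$nodes$class == "lncRNA"),
              sum(x$nodes$class == "mRNA"), x$r_min))
  invisible(x)
}

#' Build the genome-wide ceRNA network
#'
#' An edge joins lncRNA L and coding gene G when (i) they share at least
#' one expressed miRNA that binds L (lncRNA-side table) and targets G
#' with high confidence (mRNA-side table), (ii) Pearson r(L,G) strictly
#' exceeds `r_min`, and (iii) the Bonferroni-corrected correlation p is
#' below `alpha`. Every candidate shared-miRNA pair must be covered by
#' the correlation result, which must therefore be computed genome-wide
#' first.
#'
#' @param lnc_bindings miRNA-lncRNA `interaction_table` (used as given).
#' @param mrna_bindings_hc high-confidence miRNA-mRNA
#'   `interaction_table` (see [high_confidence_mrna_targets()]).
#' @param expressed_mirnas character vector of expressed miRNA ids.
#' @param cr a `corr_result` covering all candidate pairs.
#' @param config an [analysis_config()]; supplies `cerna_r_min`.
#' @param alpha Bonferroni significance level.
#' @return A `cerna_network`: `edges` (lnc_id, mrna_id, shared_mirnas
#'   list-column, r, p, p_bonf), `nodes` with class and degree, and the
#'   thresholds used.
#' @export
build_network <- function(lnc_bindings, mrna_bindings_hc, expressed_mirnas,
                          cr, config = analysis_config(), alpha = 0.05) {
  shared <- shared_mirna_map(lnc_bindings, mrna_bindings_hc,
                             expressed_mirnas)
  key <- paste(cr$pairs$lnc_id, cr$pairs$coding_id, sep = "\r")
  cand <- names(shared)
  hit <- match(cand, key)
  if (anyNA(hit)) {
    bad <- strsplit(cand[which(is.na(hit))[1]], "\r", fixed = TRUE)[[1]]
    stop("build_network: correlations must be computed genome-wide ",
         "first; missing pair ", bad[1], " - ", bad[2])
  }
  r <- cr$pairs$r[hit]
  p_bonf <- cr$pairs$p_bonf[hit]
  keep <- r > config$cerna_r_min & p_bonf < alpha
  edges <- data.frame(
    lnc_id = cr$pairs$lnc_id[hit][keep],
    mrna_id = cr$pairs$coding_id[hit][keep],
    stringsAsFactors = FALSE)
  edges$shared_mirnas <- I(lapply(shared[cand[keep]], unique))
  edges$r <- r[keep]
  edges$p <- cr$pairs$p[hit][keep]
  edges$p_bonf <- p_bonf[keep]
  edges <- edges[order(edges$lnc_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  new_cerna_network(edges, r_min = config$cerna_r_min, alpha = alpha,
                    m_tested = cr$m_tested)
}

#' Power-law fit of the network degree distribution
#'
#' Ordinary least squares of log10 degree frequency on log10 degree. By
#' default each distinct observed degree is one point; geometric
#' log-binning (frequencies summed per bin and divided by bin width,
#' plotted at the geometric bin center) is available for noisy empirical
#' distributions. The scale-free verdict is `r_squared >= r2_min`.
#'
#' @param net a `cerna_network`, or a bare integer degree vector.
#' @param node_class `"lncRNA"` or `"mRNA"` (ignored for a bare vector).
#' @param log_bins number of geometric bins, or `NULL` for none.
#' @param r2_min R-squared above which the fit is called scale-free.
#' @return list with `slope`, `r_squared`, `scale_free`, `fit_points`.
#' @export
degree_powerlaw_fit <- function(net, node_class = c("lncRNA", "mRNA"),
                                log_bins = NULL, r2_min = 0.8) {
  if (inherits(net, "cerna_network")) {
    node_class <- match.arg(node_class)
    deg <- net$nodes$degree[net$nodes$class == node_class]
  } else {
    deg <- as.integer(net)
  }
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 10)
    stop("degree_powerlaw_fit: need >= 10 distinct degree values")
  if (is.null(log_bins)) {
    tab <- table(deg)
    x <- log10(as.numeric(names(tab)))
    y <- log10(as.numeric(tab))
  } else {
    edges_b <- 10^seq(log10(min(deg)), log10(max(deg) + 1),
                      length.out = log_bins + 1)
    cut_idx <- cut(deg, breaks = edges_b, include.lowest = TRUE)
    cnt <- tapply(deg, cut_idx, length)
    keep <- !is.na(cnt) & cnt > 0
    width <- diff(edges_b)[keep]
    ctr <- sqrt(edges_b[-length(edges_b)] * edges_b[-1])[keep]
    x <- log10(ctr)
    y <- log10(cnt[keep] / width)
  }
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  list(slope = unname(stats::coef(fit)[2]), r_squared = r2,
       scale_free = r2 >= r2_min,
       fit_points = data.frame(log10_degree = x, log10_freq = y))
}

#' Induced subnetwork for selected lncRNAs
#'
#' Keeps the edges of the requested lncRNAs, recomputes degrees on the
#' subnetwork and reports the union of mediating miRNAs.
#'
#' @param net a `cerna_network`.
#' @param lnc_ids lncRNA ids present in the network.
#' @return list with `network` (a `cerna_network`) and `mirnas`.
#' @export
extract_subnetwork <- function(net, lnc_ids) {
  unknown <- setdiff(lnc_ids, net$nodes$node_id[net$nodes$class == "lncRNA"])
  if (length(unknown))
    stop("extract_subnetwork: unknown id: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  edges <- net$edges[net$edges$lnc_id %in% lnc_ids, , drop = FALSE]
  rownames(edges) <- NULL
  sub <- new_cerna_network(edges, net$r_min, net$alpha, net$m_tested)
  list(network = sub,
       mirnas = unique(unlist(edges$shared_mirnas, use.names = FALSE)))
}

#' Interactor sets per lncRNA
#' @param net a `cerna_network`.
#' @return named list: coding interactors per lncRNA.
#' @export
interactors_by_lncrna <- function(net) {
  split(net$edges$mrna_id, net$edges$lnc_id)
}
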