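#' Gene annotation table
#'
#' Constructs and validates the gene table used for all genomic distance,
#' cluster and region analyses. Coordinates are held internally as 0-based
#' half-open intervals; the transcription start site (TSS) is `start` on the
#' plus strand and `end - 1` on the minus strand.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param biotype one of `"coding"`, `"lncRNA"`, `"novel_lncRNA"`,
#'   `"miRNA"` per gene.
#' @param chrom chromosome name per gene.
#' @param start,end 0-based half-open interval per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `biotype`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
gene_table <- function(gene_id, biotype, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  biotype <- rep_len(as.character(biotype), n)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  if (anyDuplicated(gene_id))
    stop("gene_table: duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)])[1:3], collapse = ", "))
  biotypes <- c("coding", "lncRNA", "novel_lncRNA", "miRNA")
  if (!all(biotype %in% biotypes))
    stop("gene_table: unknown biotype: ",
         paste(setdiff(unique(biotype), biotypes), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("gene_table: strand must be '+' or '-'")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("gene_table: start must be < end")
  tss <- ifelse(strand == "+", start, end - 1)
  gt <- data.frame(gene_id = gene_id, biotype = as.character(biotype),
                   chrom = as.character(chrom), start = start, end = end,
                   strand = as.character(strand), tss = tss,
                   stringsAsFactors = FALSE)
  class(gt) <- c("gene_table", "data.frame")
  gt
}

as_granges <- function(gt) {
  GenomicRanges::GRanges(
    seqnames = gt$chrom,
    ranges = IRanges::IRanges(start = gt$start + 1, end = gt$end),
    strand = gt$strand, gene_id = gt$gene_id)
}

#' Expression matrix with sample metadata
#'
#' Holds a genes-by-samples expression matrix, its scale
#' (`tpm -> log2 -> log2_quantile -> adjusted`), and per-sample metadata.
#' Metadata must carry a `group` factor; `batch` and `immune_fraction`
#' are used by the adjustment and DE stages when present.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param meta data.frame with one row per sample (rownames or column
#'   `sample_id` matching `colnames(values)`), including `group`.
#' @param scale one of `"tpm"`, `"log2"`, `"log2_quantile"`, `"adjusted"`.
#' @return An object of class `expr_matrix`: list with elements `values`,
#'   `meta`, `scale`.
#' @export
expr_matrix <- function(values, meta, scale = "tpm") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expr_matrix: values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expr_matrix: values must carry gene and sample dimnames")
  if (anyNA(values)) stop("expr_matrix: missing values not allowed")
  scale <- match.arg(scale, c("tpm", "log2", "log2_quantile", "adjusted"))
  if (scale == "tpm" && any(values < 0))
    stop("expr_matrix: negative TPM value")
  if (!is.null(meta$sample_id)) rownames(meta) <- meta$sample_id
  missing <- setdiff(colnames(values), rownames(meta))
  if (length(missing))
    stop("expr_matrix: samples missing from metadata: ",
         paste(utils::head(missing, 3), collapse = ", "))
  meta <- meta[colnames(values), , drop = FALSE]
  if (is.null(meta$group)) stop("expr_matrix: metadata must have 'group'")
  meta$group <- as.factor(meta$group)
  if (!is.null(meta$immune_fraction)) {
    f <- meta$immune_fraction
    if (any(f < 0 | f > 1)) stop("expr_matrix: immune_fraction outside [0,1]")
  }
  em <- list(values = values, meta = meta, scale = scale)
  class(em) <- "expr_matrix"
  em
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale=%s\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$meta$group)),
                               table(x$meta$group)), collapse = " "), "\n")
  invisible(x)
}

#' Number of samples in an expression matrix
#' @param em an `expr_matrix`.
#' @return integer sample count.
#' @export
n_samples <- function(em) ncol(em$values)

# internal: enforce the one-way scale progression
advance_scale <- function(em, from, to) {
  if (!identical(em$scale, from))
    stop("expected scale '", from, "', got '", em$scale, "'")
  em$scale <- to
  em
}

#' miRNA-target interaction table
#'
#' @param mirna_id,target_id edge endpoints.
#' @param target_kind `"lncRNA"` or `"mRNA"` per edge.
#' @param evidence `"experimental"` or `"predicted"` per edge.
#' @param source free-text provenance per edge.
#' @return data.frame of class `interaction_table` with duplicate
#'   `(mirna_id, target_id, evidence)` rows removed.
#' @export
interaction_table <- function(mirna_id, target_id, target_kind, evidence,
                              source = "") {
  if (!all(evidence %in% c("experimental", "predicted")))
    stop("interaction_table: evidence must be one of ",
         "'experimental', 'predicted'; got: ",
         paste(setdiff(unique(evidence), c("experimental", "predicted")),
               collapse = ", "))
  if (!all(target_kind %in% c("lncRNA", "mRNA")))
    stop("interaction_table: target_kind must be 'lncRNA' or 'mRNA'")
  it <- data.frame(mirna_id = as.character(mirna_id),
                   target_id = as.character(target_id),
                   target_kind = as.character(target_kind),
                   evidence = as.character(evidence),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  it <- it[!duplicated(it[c("mirna_id", "target_id", "evidence")]), ,
           drop = FALSE]
  rownames(it) <- NULL
  class(it) <- c("interaction_table", "data.frame")
  it
}

#' Gene set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of descriptions.
#' @return list of class `gene_sets` with elements `sets`, `descriptions`.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene_sets: every set must be named")
  if (any(lengths(sets) < 1)) stop("gene_sets: empty gene set")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  gs <- list(sets = lapply(sets, as.character),
             descriptions = descriptions)
  class(gs) <- "gene_sets"
  gs
}

#' Resolve gene-set members against a gene table
#'
#' Drops members absent from `gt`, reporting the dropped count via a
#' message; sets left empty are removed.
#'
#' @param gs a `gene_sets` collection.
#' @param gt a `gene_table`.
#' @return filtered `gene_sets`.
#' @export
resolve_gene_sets <- function(gs, gt) {
  known <- gt$gene_id
  dropped <- 0L
  sets <- lapply(gs$sets, function(s) {
    keep <- s %in% known
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0)
    message("resolve_gene_sets: dropped ", dropped, " unresolved members")
  keep <- lengths(sets) >= 1
  gene_sets(sets[keep], gs$descriptions[names(sets)[keep]])
}

# internal constructor for hypothesis-test results
test_result <- function(statistic, p, alternative, method, ...) {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  res <- c(list(statistic = unname(statistic), p = min(unname(p), 1),
                alternative = alternative, method = method),
           list(...))
  class(res) <- "cerna_test"
  res
}

#' @export
print.cerna_test <- function(x, ...) {
  cat(x$method, " (", x$alternative, ")\n", sep = "")
  cat("  statistic =", format(x$statistic), "  p =", format(x$p), "\n")
  extras <- setdiff(names(x), c("statistic", "p", "alternative", "method"))
  for (nm in extras)
    cat("  ", nm, " = ", paste(format(x[[nm]]), collapse = " "), "\n",
        sep = "")
  invisible(x)
}
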