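#' Read gene-level records from a GTF file
#'
#' Imports via rtracklayer, keeps `gene` feature records, converts the
#' 1-based inclusive GTF coordinates to the package's 0-based half-open
#' convention and derives the TSS by strand. Biotypes are taken from the
#' `gene_biotype` (or `gene_type`) attribute and mapped onto
#' coding/lncRNA/novel_lncRNA/miRNA.
#'
#' @param path GTF file.
#' @param biotype_map named character vector mapping raw biotype strings to
#'   the internal vocabulary; defaults cover the common GENCODE names.
#' @param default_biotype biotype assigned to unmapped values, or `NULL`
#'   to raise an error on them.
#' @return A `gene_table`.
#' @export
read_gtf <- function(path,
                     biotype_map = c(protein_coding = "coding",
                                     coding = "coding",
                                     lncRNA = "lncRNA",
                                     lincRNA = "lncRNA",
                                     novel_lncRNA = "novel_lncRNA",
                                     miRNA = "miRNA"),
                     default_biotype = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors_mcols(gr)))
    gr <- gr[S4Vectors_mcols(gr)$type == "gene"]
  mc <- S4Vectors_mcols(gr)
  if (!"gene_id" %in% names(mc)) stop("read_gtf: records lack gene_id")
  raw_bt <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype
            else if ("gene_type" %in% names(mc)) mc$gene_type
            else stop("read_gtf: records lack a biotype attribute")
  bt <- unname(biotype_map[raw_bt])
  if (anyNA(bt)) {
    if (is.null(default_biotype))
      stop("read_gtf: unknown biotype: ",
           paste(unique(raw_bt[is.na(bt)]), collapse = ", "))
    bt[is.na(bt)] <- default_biotype
  }
  ids <- as.character(mc$gene_id)
  if (anyDuplicated(ids))
    stop("read_gtf: duplicate gene_id: ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  gene_table(gene_id = ids, biotype = bt,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

# avoid a hard S4Vectors import for one accessor
S4Vectors_mcols <- function(x) GenomicRanges::mcols(x)

#' Write a gene table as GTF gene records
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are
#' emitted as 1-based inclusive GTF.
#'
#' @param gt a `gene_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gt, path) {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', gt$gene_id,
                   gt$biotype)
  lines <- paste(gt$chrom, "cernet", "gene", gt$start + 1, gt$end, ".",
                 gt$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has gene ids in the first column and sample ids in the
#' header; the metadata TSV is keyed by `sample_id` and must cover every
#' sample in the matrix.
#'
#' @param matrix_path expression TSV.
#' @param meta_path metadata TSV with at least `sample_id` and `group`.
#' @param scale scale tag of the stored values (default `"tpm"`).
#' @return An `expr_matrix`.
#' @export
read_expression <- function(matrix_path, meta_path, scale = "tpm") {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("read_expression: duplicate gene id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("read_expression: duplicated sample id")
  if (!is.numeric(m)) stop("read_expression: non-numeric cell")
  rownames(m) <- ids
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("read_expression: metadata lacks sample_id column")
  expr_matrix(m, meta, scale = scale)
}

#' Write an expression matrix (values only) to TSV
#'
#' @param em an `expr_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table from TSV
#'
#' Requires columns `mirna_id`, `target_id`, `target_kind`, `evidence`;
#' `source` is optional.
#'
#' @param path TSV file.
#' @return An `interaction_table`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_kind", "evidence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_interactions: missing required column: ",
         paste(miss, collapse = ", "))
  interaction_table(df$mirna_id, df$target_id, df$target_kind, df$evidence,
                    if (is.null(df$source)) "" else df$source)
}

#' Write an interaction table to TSV
#' @param it an `interaction_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(it, path) {
  utils::write.table(it, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated: name, description,
#' members.
#'
#' @param path GMT file.
#' @return A `gene_sets` collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("read_gmt: line ", bad[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_sets(stats::setNames(sets, nm), stats::setNames(desc, nm))
}

#' Write gene sets in GMT format
#' @param gs a `gene_sets` collection.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$descriptions[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ceRNA network edge list to TSV
#'
#' Columns: `lnc_id`, `mrna_id`, `shared_mirnas` (';'-joined), `r`, `p`,
#' `p_bonf`. Provenance (thresholds) is recorded in `#`-prefixed header
#' lines.
#'
#' @param net a `cerna_network` (see [build_network()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cernet ceRNA network: r_min=%g alpha=%g m_tested=%d",
                     net$r_min, net$alpha, net$m_tested), con)
  edges <- net$edges
  edges$shared_mirnas <- vapply(edges$shared_mirnas, paste, "",
                                collapse = ";")
  utils::write.table(edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ceRNA network edge list written by [write_network()]
#' @param path TSV file.
#' @return A `cerna_network`.
#' @export
read_network <- function(path) {
  header <- readLines(path, n = 1)
  grab <- function(key) as.numeric(sub(sprintf(".*%s=([^ ]+).*", key),
                                       "\\1", header))
  prov <- c(grab("r_min"), grab("alpha"), grab("m_tested"))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("lnc_id", "mrna_id", "shared_mirnas", "r", "p", "p_bonf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_network: missing required column: ",
         paste(miss, collapse = ", "))
  df$shared_mirnas <- strsplit(df$shared_mirnas, ";", fixed = TRUE)
  new_cerna_network(df, r_min = prov[1], alpha = prov[2],
                    m_tested = as.integer(prov[3]))
}

#' Write any data.frame result table to TSV
#' @param obj data.frame.
#' @param path output TSV.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(obj, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GWAS-style locus list
#'
#' TSV with columns `chrom`, `position` (1-based) and optional `label`.
#'
#' @param path TSV file.
#' @return data.frame with 0-based `position` column `pos0`.
#' @export
read_loci <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "position"), names(df))
  if (length(miss))
    stop("read_loci: missing required column: ",
         paste(miss, collapse = ", "))
  df$pos0 <- df$position - 1
  df
}
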