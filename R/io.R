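#' Write / read a gene x sample expression matrix as TSV
#'
#' Genes as rows; first column `gene`, remaining columns samples.
#'
#' @param expression gene x sample matrix.
#' @param path output file.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv`: the numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Load an expression cohort from TSV files
#'
#' Reads an expression matrix (see [read_expression_tsv()]) and a clinical
#' table (columns `sample`, `time`, `event`, optionally a donor column and a
#' numeric deduplication column such as tumor cellularity). When `dedup_col`
#' is given, one sample per donor is kept: the one maximizing that column
#' (ties broken by sample id). Records with non-positive time are dropped
#' and counted; samples lacking either expression or clinical data are
#' dropped with a message.
#'
#' @param expression_path,clinical_path TSV file paths.
#' @param id cohort id (default: expression file stem).
#' @param dedup_col optional numeric clinical column used for per-donor
#'   deduplication.
#' @param donor_col clinical column naming the donor (default `"donor"`).
#' @return an [expression_cohort()].
#' @export
load_expression_cohort <- function(expression_path, clinical_path,
                                   id = NULL, dedup_col = NULL,
                                   donor_col = "donor") {
  if (is.null(id))
    id <- sub("\\.[^.]*$", "", basename(expression_path))
  expr <- read_expression_tsv(expression_path)
  clin <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(clin)))
    stop("clinical table must have columns sample, time, event")
  if (!is.null(dedup_col)) {
    if (!all(c(dedup_col, donor_col) %in% names(clin)))
      stop("deduplication needs columns ", donor_col, " and ", dedup_col)
    ord <- order(clin[[donor_col]], -clin[[dedup_col]], clin$sample)
    clin <- clin[ord, , drop = FALSE]
    dup <- duplicated(clin[[donor_col]])
    if (any(dup))
      message(id, ": kept 1 of ", sum(dup) + length(unique(clin[[donor_col]][dup])),
              " samples per duplicated donor by highest ", dedup_col)
    clin <- clin[!dup, , drop = FALSE]
  }
  expression_cohort(id, expr, clin)
}

#' Write an expression cohort (expression + clinical TSV)
#'
#' @param cohort an [expression_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, paste0(cohort$id, "_expression.tsv"))
  cp <- file.path(dir, paste0(cohort$id, "_clinical.tsv"))
  write_expression_tsv(cohort$expression, ep)
  utils::write.table(cohort$survival, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = ep, clinical = cp))
}

#' Export a gene network as an edge-list TSV (geneA, geneB, rho)
#' @param network a [build_gcn()] result.
#' @param path output file.
#' @export
write_network_tsv <- function(network, path) {
  el <- igraph::as_data_frame(network$graph, what = "edges")
  names(el) <- c("geneA", "geneB", "rho")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA)
}

#' Spearman concordance of mean expression between two cohorts
#'
#' Computes each gene's mean FPKM in both cohorts over the shared genes and
#' returns the Spearman correlation -- the standard cross-cohort QC check.
#'
#' @param cohort_a,cohort_b [expression_cohort()] objects.
#' @return Spearman rho.
#' @export
cohort_expression_concordance <- function(cohort_a, cohort_b) {
  shared <- intersect(rownames(cohort_a$expression),
                      rownames(cohort_b$expression))
  if (length(shared) < 10) stop("fewer than 10 shared genes")
  stats::cor(rowMeans(cohort_a$expression[shared, , drop = FALSE]),
             rowMeans(cohort_b$expression[shared, , drop = FALSE]),
             method = "spearman")
}
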