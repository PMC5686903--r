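#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV file with a header row and a first column of identifiers
#' and returns the matrix in the package's canonical samples-x-genes
#' orientation, regardless of how the file is laid out. Expression files in
#' the wild are usually genes-in-rows (one row per gene, one column per
#' sample), which is the default dialect.
#'
#' @param path path to a delimited text file.
#' @param orientation `"genes_in_rows"` (default: rows are genes, columns are
#'   samples) or `"samples_in_rows"`.
#' @param impute missing-value policy: `"none"` (default) rejects any missing
#'   cell; `"gene_mean"` replaces missing entries by the mean of the
#'   non-missing values of the same gene.
#' @param sep field separator, tab by default.
#' @return a numeric matrix with samples in rows and genes in columns,
#'   `rownames` = sample ids, `colnames` = gene ids.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                            impute = c("none", "gene_mean"), sep = "\t") {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  raw <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(raw) < 2L) stop("expression file needs an id column plus at least one value column")
  row_ids <- as.character(raw[[1L]])
  col_ids <- colnames(raw)[-1L]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup)) stop("duplicated row identifiers: ", paste(dup, collapse = ", "))
  dup <- unique(col_ids[duplicated(col_ids)])
  if (length(dup)) stop("duplicated column identifiers: ", paste(dup, collapse = ", "))

  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(is.na(vals) & !is.na(as.matrix(raw[, -1L, drop = FALSE])), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(row_ids, col_ids)

  E <- if (orientation == "genes_in_rows") t(vals) else vals
  if (anyNA(E)) {
    if (impute == "none") {
      idx <- which(is.na(E), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at sample '%s', gene '%s' (set impute = \"gene_mean\" to impute)",
                   rownames(E)[idx[1L]], colnames(E)[idx[2L]]))
    }
    n_imp <- sum(is.na(E))
    for (j in which(colSums(is.na(E)) > 0L)) {
      mu <- mean(E[, j], na.rm = TRUE)
      if (is.nan(mu)) stop("gene '", colnames(E)[j], "' has no observed values to impute from")
      E[is.na(E[, j]), j] <- mu
    }
    message(sprintf("imputed %d missing values by per-gene means", n_imp))
  }
  validate_expression(E)
}

# Shared invariants of the internal samples-x-genes matrix.
validate_expression <- function(E) {
  if (!is.matrix(E) || !is.numeric(E)) stop("expression matrix must be a numeric matrix")
  if (nrow(E) < 2L || ncol(E) < 2L) stop("expression matrix needs at least 2 samples and 2 genes")
  if (is.null(rownames(E)) || is.null(colnames(E))) stop("expression matrix needs sample and gene identifiers")
  if (anyDuplicated(rownames(E))) stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(E))) stop("duplicated gene identifiers")
  if (anyNA(E) || any(!is.finite(E))) stop("expression matrix contains missing or non-finite values")
  E
}

#' Write an expression matrix to a TSV file
#'
#' Inverse of [read_expression()]; by default writes the common
#' genes-in-rows dialect. `read_expression(write_expression(E))` reproduces
#' `E` up to numeric printing precision (15 significant digits).
#'
#' @param E samples-x-genes numeric matrix with dimnames.
#' @param path output path.
#' @param orientation file layout, as in [read_expression()].
#' @export
write_expression <- function(E, path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  validate_expression(E)
  out <- if (orientation == "genes_in_rows") t(E) else E
  df <- data.frame(id = rownames(out), format(out, digits = 15, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- "id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to a gene list
#'
#' Keeps the columns whose identifiers appear in `gene_list`, preserving the
#' original column order of `E` (the list order does not matter). This is how
#' an intrinsic gene list is applied to a genome-wide matrix before
#' clustering.
#'
#' @param E samples-x-genes matrix.
#' @param gene_list character vector of gene identifiers to keep.
#' @return the restricted matrix; the number of list entries not found in `E`
#'   is reported via `message()` and attached as attribute `"n_unmatched"`.
#' @export
subset_genes <- function(E, gene_list) {
  validate_expression(E)
  if (length(gene_list) == 0L) stop("gene_list is empty")
  gene_list <- unique(as.character(gene_list))
  keep <- colnames(E) %in% gene_list
  if (!any(keep)) stop("no genes of the list are present in the matrix")
  n_unmatched <- sum(!gene_list %in% colnames(E))
  if (n_unmatched > 0L) {
    message(sprintf("%d of %d listed genes not present in the matrix", n_unmatched, length(gene_list)))
  }
  out <- E[, keep, drop = FALSE]
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Read a sample label vector
#'
#' Two-column TSV `sample_id<TAB>label` with a header row, e.g. PAM50 calls
#' or ER/PR status. Missing labels may be written as `NA`.
#'
#' @param path path to the labels file.
#' @return named character vector: `names` are sample ids, values the labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("labels file needs columns sample_id and label")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated sample identifiers in labels file")
  stats::setNames(as.character(df[[2L]]), ids)
}

#' Write a sample label vector
#'
#' @param labels named character vector (names = sample ids).
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The six genomic region categories used for CpG annotation
#'
#' TSS200, TSS1500, 5'UTR and 1st exon lie in the promoter region of a gene;
#' gene body and 3'UTR do not.
#' @export
REGION_CATEGORIES <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "GeneBody", "3'UTR")

#' Read a methylation beta-value matrix
#'
#' CpG sites in rows, samples in columns; values must lie in `[0, 1]` or be
#' `NA` (missing probes are allowed and excluded from downstream means).
#'
#' @param path path to the beta TSV (first column = CpG id, header = samples).
#' @return numeric matrix CpGs x samples.
#' @export
read_methylation <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicated CpG identifiers")
  beta <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- ids
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values must lie in [0, 1]")
  beta
}

#' Read a CpG region annotation
#'
#' Two-column TSV `cpg_id<TAB>region`; the region must be one of
#' [REGION_CATEGORIES].
#'
#' @param path path to the annotation file.
#' @return named character vector: names = CpG ids, values = region category.
#' @export
read_region_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) stop("annotation file needs columns cpg_id and region")
  region <- as.character(df[[2L]])
  bad <- setdiff(unique(region), REGION_CATEGORIES)
  if (length(bad)) {
    stop("unknown region categories: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(REGION_CATEGORIES, collapse = ", "), ")")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated CpG identifiers in annotation")
  stats::setNames(region, ids)
}
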