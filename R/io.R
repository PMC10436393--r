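#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects tab-separated text: a header of sample identifiers, genes as
#' rows, first column the gene identifier, all remaining cells numeric
#' log2-scale values. Duplicate gene identifiers and non-numeric cells are
#' rejected with the offending line reported.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples: ", path)
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) & df[, -1, drop = FALSE] != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value at line ", bad[1, 1] + 1L, ", sample '",
         colnames(m)[bad[1, 2]], "'")
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' Tab separator, '.' decimal point, no quoting; first column `gene`. Full
#' double precision (up to 15 significant digits) so a read/write cycle is
#' byte-stable.
#'
#' @param expr numeric matrix with gene rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical/annotation table from CSV
#'
#' Comma-separated with header; `sample_id` column required.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical table lacks a sample_id column: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ", path)
  df
}

#' Write a table as CSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform linear expression values
#'
#' `log2(1 + v)` elementwise, the transform applied to FPKM/RPKM-scale
#' quantifications before any analysis step.
#'
#' @param values non-negative numeric values.
#' @return log2-scale values.
#' @examples
#' log_transform(c(0, 1, 3))  # 0 1 2
#' @export
log_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("negative expression values cannot be log-transformed")
  log2(1 + values)
}
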