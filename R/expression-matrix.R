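#' Read a gene expression matrix from delimited text
#'
#' Reads a genes-by-samples expression table (TSV or CSV, optionally
#' gzip-compressed) into a numeric matrix with gene identifiers as row names
#' and sample identifiers as column names. Duplicate gene identifiers --
#' typical after probe-to-gene mapping -- are collapsed to a single row by the
#' per-sample arithmetic mean. Non-numeric cells become `NA`; missing values
#' are first-class throughout the package because the classifier has an
#' explicit fallback for undetected genes.
#'
#' The expression scale is irrelevant: every downstream computation uses only
#' within-sample orderings, so log2 intensities, TPM and raw counts are all
#' acceptable as long as each sample's values are on one monotone-consistent
#' scale.
#'
#' @param path Path to a delimited text file. Files ending in `.csv` or
#'   `.csv.gz` are read as comma-separated, anything else as tab-separated
#'   unless `sep` is given.
#' @param id_column Name or index of the column holding gene identifiers
#'   (default: first column).
#' @param sep Field separator; `NULL` (default) auto-detects from the file
#'   extension.
#' @param orientation Either `"genes_rows"` (default, the series-matrix
#'   convention) or `"genes_cols"`; the matrix is transposed for the latter.
#'   Orientation is never guessed from the data.
#' @param collapse How to collapse duplicate gene IDs: `"mean"` (default) or
#'   `"error"`.
#' @return Numeric matrix, genes in rows, samples in columns, with unique
#'   gene-ID row names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene = c("7177", "3800"), s1 = c(1, 2), s2 = c(3, 4)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' m <- read_expression_matrix(tf)
#' dim(m)
#' @export
read_expression_matrix <- function(path, id_column = 1L, sep = NULL,
                                   orientation = c("genes_rows", "genes_cols"),
                                   collapse = c("mean", "error")) {
  orientation <- match.arg(orientation)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("expression file must contain at least one gene row and one sample column")
  }
  if (is.character(id_column)) {
    idx <- match(id_column, colnames(df))
    if (is.na(idx)) stop("id_column '", id_column, "' not found in header")
  } else {
    idx <- as.integer(id_column)
  }
  gene_ids <- as.character(df[[idx]])
  vals <- df[, -idx, drop = FALSE]
  mat <- vapply(vals, function(x) suppressWarnings(as.numeric(x)),
                numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  rownames(mat) <- gene_ids
  if (orientation == "genes_cols") {
    mat <- t(mat)
    # after transposition the original header row held gene ids
  }
  mat <- collapse_duplicate_genes(mat, method = collapse)
  validate_expression_matrix(mat)
  mat
}

#' Collapse duplicate gene rows of an expression matrix
#'
#' @param mat Numeric matrix with gene IDs as row names.
#' @param method `"mean"` collapses duplicated IDs to their per-sample
#'   arithmetic mean (ignoring `NA`); `"error"` fails on any duplicate.
#' @return Matrix with unique row names, in first-appearance order.
#' @export
collapse_duplicate_genes <- function(mat, method = c("mean", "error")) {
  method <- match.arg(method)
  ids <- rownames(mat)
  if (is.null(ids)) stop("matrix must have gene-ID row names")
  if (!anyDuplicated(ids)) return(mat)
  if (method == "error") stop("duplicate gene IDs present: ",
                              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  uniq <- unique(ids)
  out <- rowsum(ifelse(is.na(mat), 0, mat), group = ids, reorder = FALSE) /
    rowsum((!is.na(mat)) * 1, group = ids, reorder = FALSE)
  out[is.nan(out)] <- NA_real_
  out <- out[uniq, , drop = FALSE]
  colnames(out) <- colnames(mat)
  out
}

validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression data must be a numeric matrix")
  }
  if (nrow(mat) < 2L) {
    stop("expression matrix must contain at least two genes after collapsing duplicates")
  }
  if (ncol(mat) < 1L) stop("expression matrix has no samples")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("gene IDs must be present and unique")
  }
  invisible(mat)
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric genes-by-samples matrix with gene-ID row names.
#' @param path Output file path.
#' @param id_column Header for the gene-ID column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  validate_expression_matrix(mat)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample label table
#'
#' Label tables are two-column TSV files (`sample_id`, `label`). Labels are
#' returned as a named character vector keyed by sample ID.
#'
#' @param path File path.
#' @param vocabulary Optional character vector of allowed labels; any label
#'   outside it is an error.
#' @return Named character vector of labels.
#' @export
read_label_table <- function(path, vocabulary = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("label table needs columns sample_id and label")
  labs <- as.character(df[[2]])
  names(labs) <- as.character(df[[1]])
  if (anyDuplicated(names(labs))) stop("duplicated sample IDs in label table")
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(labs), vocabulary)
    if (length(bad)) stop("labels outside declared vocabulary: ",
                          paste(bad, collapse = ", "))
  }
  labs
}

#' @rdname read_label_table
#' @param labels Named character vector of labels.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels), label = unname(labels)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Check that every sample in `sample_ids` has a label; returns labels in that order.
match_labels <- function(labels, sample_ids) {
  miss <- setdiff(sample_ids, names(labels))
  if (length(miss)) {
    stop("no label for sample(s): ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  }
  labels[sample_ids]
}
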