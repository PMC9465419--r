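#' Construct an REO gene-pair signature
#'
#' A signature is an ordered set of gene pairs with the convention that the
#' within-sample pattern `expression(gene_a) > expression(gene_b)` is a vote
#' FOR the signature's positive class. Each gene may appear in at most one
#' pair (the de-redundancy contract): this makes the majority vote robust to
#' single-gene dropout in degraded specimens.
#'
#' @param pairs data.frame with character columns `gene_a`, `gene_b` and
#'   optional `symbol_a`, `symbol_b`.
#' @param name Signature name (e.g. `"NE-signature"`).
#' @param positive_label Label voted for by the `gene_a > gene_b` pattern.
#' @param negative_label Label assigned when the vote fails.
#' @return Object of class `reo_signature`.
#' @export
reo_signature <- function(pairs, name, positive_label, negative_label) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% colnames(pairs))) {
    stop("pairs must have columns gene_a and gene_b")
  }
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (!"symbol_a" %in% colnames(pairs)) pairs$symbol_a <- rep(NA_character_, nrow(pairs))
  if (!"symbol_b" %in% colnames(pairs)) pairs$symbol_b <- rep(NA_character_, nrow(pairs))
  sig <- structure(
    list(name = as.character(name),
         positive_label = as.character(positive_label),
         negative_label = as.character(negative_label),
         pairs = pairs[, c("gene_a", "gene_b", "symbol_a", "symbol_b")]),
    class = "reo_signature")
  validate_signature(sig)
  sig
}

validate_signature <- function(sig) {
  p <- sig$pairs
  if (nrow(p) == 0L) stop("signature '", sig$name, "' has no gene pairs")
  if (any(p$gene_a == p$gene_b)) {
    stop("signature '", sig$name, "' contains a pair with identical genes")
  }
  genes <- c(p$gene_a, p$gene_b)
  if (anyDuplicated(genes)) {
    stop("signature '", sig$name, "' violates the one-pair-per-gene rule: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (identical(sig$positive_label, sig$negative_label)) {
    stop("positive and negative labels must differ")
  }
  invisible(sig)
}

#' @export
print.reo_signature <- function(x, ...) {
  cat("REO signature '", x$name, "': ", nrow(x$pairs), " gene pairs\n", sep = "")
  cat("  gene_a > gene_b votes for '", x$positive_label,
      "' (else '", x$negative_label, "')\n", sep = "")
  shown <- utils::head(x$pairs, 5)
  lab <- function(sym, id) ifelse(is.na(sym), id, sprintf("%s (%s)", sym, id))
  for (i in seq_len(nrow(shown))) {
    cat("  ", lab(shown$symbol_a[i], shown$gene_a[i]), " > ",
        lab(shown$symbol_b[i], shown$gene_b[i]), "\n", sep = "")
  }
  if (nrow(x$pairs) > 5) cat("  ... and", nrow(x$pairs) - 5, "more pairs\n")
  invisible(x)
}

#' @export
length.reo_signature <- function(x) nrow(x$pairs)

#' Genes used by a signature or panel
#'
#' @param x An `reo_signature` or `reo_panel`.
#' @return Character vector of gene identifiers (unique for a panel).
#' @export
signature_genes <- function(x) {
  if (inherits(x, "reo_signature")) return(c(x$pairs$gene_a, x$pairs$gene_b))
  if (inherits(x, "reo_panel")) {
    return(unique(unlist(lapply(x$steps, signature_genes))))
  }
  stop("x must be an reo_signature or reo_panel")
}

#' Read and write signature files
#'
#' Signatures are stored as TSV with header comments carrying the name and
#' class labels, followed by columns `gene_a_entrez`, `gene_b_entrez`,
#' `gene_a_symbol`, `gene_b_symbol`. Writing then reading reproduces the
#' signature exactly.
#'
#' @param path File path.
#' @return `read_signature_file` returns an `reo_signature`.
#' @export
read_signature_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (!length(m)) stop("signature file missing header field '", key, "'")
    sub(paste0("^#\\s*", key, "\\s*=\\s*"), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = paste(body, collapse = "\n"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_a_entrez", "gene_b_entrez")
  if (!all(need %in% colnames(df))) {
    stop("signature file must have columns gene_a_entrez and gene_b_entrez")
  }
  pairs <- data.frame(gene_a = df$gene_a_entrez, gene_b = df$gene_b_entrez,
                      stringsAsFactors = FALSE)
  blank_to_na <- function(x) ifelse(is.na(x) | x == "", NA_character_, x)
  pairs$symbol_a <- if ("gene_a_symbol" %in% colnames(df)) blank_to_na(df$gene_a_symbol) else NA_character_
  pairs$symbol_b <- if ("gene_b_symbol" %in% colnames(df)) blank_to_na(df$gene_b_symbol) else NA_character_
  reo_signature(pairs, name = get_field("name"),
                positive_label = get_field("positive_label"),
                negative_label = get_field("negative_label"))
}

#' @rdname read_signature_file
#' @param sig An `reo_signature`.
#' @export
write_signature_file <- function(sig, path) {
  validate_signature(sig)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name=", sig$name),
               paste0("# positive_label=", sig$positive_label),
               paste0("# negative_label=", sig$negative_label)), con)
  na_to_blank <- function(x) ifelse(is.na(x), "", x)
  df <- data.frame(gene_a_entrez = sig$pairs$gene_a,
                   gene_b_entrez = sig$pairs$gene_b,
                   gene_a_symbol = na_to_blank(sig$pairs$symbol_a),
                   gene_b_symbol = na_to_blank(sig$pairs$symbol_b),
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
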