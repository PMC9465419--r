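#' Evaluate the REO pattern of one gene pair in one sample
#'
#' The within-sample relative expression ordering of a pair is `"GT"` when
#' `value(gene_a) > value(gene_b)`, `"LE"` when both values are present and
#' `value(gene_a) <= value(gene_b)` (a tie falls in the `"LE"` branch: the
#' dichotomy is exhaustive), and `"MISSING"` when either gene is absent from
#' the sample or its value is `NA`.
#'
#' @param sample_values Named numeric vector of expression values.
#' @param gene_a,gene_b Gene identifiers of the pair.
#' @return `"GT"`, `"LE"` or `"MISSING"`.
#' @export
evaluate_pair <- function(sample_values, gene_a, gene_b) {
  a <- sample_values[gene_a]
  b <- sample_values[gene_b]
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b)) return("MISSING")
  if (a > b) "GT" else "LE"
}

#' Majority-vote a signature on one sample
#'
#' Each evaluable pair votes for the positive class when its pattern is `GT`
#' and against otherwise. Pairs with a missing gene are removed and the
#' majority rule is applied to the remaining pairs: the positive class is
#' called only when strictly more than half of the evaluable pairs vote for
#' it. An exact split calls the negative class (flagged as `borderline`); no
#' evaluable pairs at all yields the call `"ABSTAIN"` (flagged
#' `no_evaluable_pairs`). Fewer evaluable pairs than
#' `min_evaluable_frac` of the signature raises a `low_coverage` flag.
#'
#' @param sample_values Named numeric vector of expression values.
#' @param signature An [reo_signature].
#' @param min_evaluable_frac Warning threshold on the evaluable fraction
#'   (default 0.5).
#' @return List with `votes_for`, `votes_against`, `n_evaluable`, `n_missing`,
#'   `call` and character vector `flags`.
#' @export
score_signature <- function(sample_values, signature, min_evaluable_frac = 0.5) {
  validate_signature(signature)
  a <- sample_values[signature$pairs$gene_a]
  b <- sample_values[signature$pairs$gene_b]
  gt <- a > b                       # NA when either side missing
  n_missing <- sum(is.na(gt))
  votes_for <- sum(gt, na.rm = TRUE)
  n_evaluable <- sum(!is.na(gt))
  votes_against <- n_evaluable - votes_for
  flags <- character(0)
  if (n_evaluable == 0L) {
    call <- "ABSTAIN"
    flags <- c(flags, "no_evaluable_pairs")
  } else if (votes_for > n_evaluable / 2) {
    call <- signature$positive_label
  } else {
    call <- signature$negative_label
    if (votes_for == n_evaluable / 2) flags <- c(flags, "borderline")
  }
  if (n_evaluable < min_evaluable_frac * nrow(signature$pairs)) {
    flags <- c(flags, "low_coverage")
  }
  list(signature = signature$name, votes_for = votes_for,
       votes_against = votes_against, n_evaluable = n_evaluable,
       n_missing = n_missing, call = call, flags = flags)
}

#' Classify one sample through a hierarchical panel
#'
#' Walks the panel's decision tree from its first signature, scoring each
#' signature encountered and following the positive/negative route until a
#' terminal label is reached. An abstention at any step (no evaluable pairs)
#' terminates with the label `"UNDETERMINED"`.
#'
#' @inheritParams score_signature
#' @param panel An [reo_panel].
#' @return List with `final_label`, `step_results` (one [score_signature]
#'   result per evaluated step) and combined `flags`.
#' @export
classify_sample <- function(sample_values, panel, min_evaluable_frac = 0.5) {
  step <- 1L
  step_results <- list()
  flags <- character(0)
  final <- NULL
  repeat {
    sig <- panel$steps[[step]]
    res <- score_signature(sample_values, sig, min_evaluable_frac)
    step_results[[sig$name]] <- res
    flags <- union(flags, res$flags)
    if (identical(res$call, "ABSTAIN")) {
      final <- "UNDETERMINED"
      break
    }
    route <- panel$routing[[step]]
    tgt <- parse_route(if (identical(res$call, sig$positive_label))
      route$on_positive else route$on_negative)
    if (tgt$type == "label") {
      final <- tgt$label
      break
    }
    step <- tgt$step
  }
  list(final_label = final, step_results = step_results, flags = flags)
}

#' Classify every sample of an expression matrix
#'
#' Per-sample batch wrapper around [classify_sample]: the result for a sample
#' depends only on that sample's column, so batches, permutations and
#' concatenations commute with classification.
#'
#' @param mat Numeric genes-by-samples matrix with gene-ID row names.
#' @param panel An [reo_panel].
#' @param min_evaluable_frac Passed to [score_signature].
#' @return A data.frame of class `reo_classification` with columns
#'   `sample_id`, `final_label`, `flags` and per-step vote columns
#'   (`<step>_votes_for`, `<step>_n_evaluable`); full step detail is kept in
#'   the `"detail"` attribute.
#' @examples
#' panel <- builtin_panel()
#' sim <- simulate_panel_archetypes(panel, n_per_label = 2, seed = 1)
#' classify_matrix(sim$matrix, panel)
#' @export
classify_matrix <- function(mat, panel, min_evaluable_frac = 0.5) {
  validate_expression_matrix(mat)
  validate_panel(panel)
  detail <- lapply(seq_len(ncol(mat)), function(j) {
    classify_sample(mat[, j], panel, min_evaluable_frac)
  })
  names(detail) <- colnames(mat)
  step_names <- vapply(panel$steps, function(s) s$name, character(1))
  out <- data.frame(
    sample_id = colnames(mat),
    final_label = vapply(detail, `[[`, character(1), "final_label"),
    stringsAsFactors = FALSE, row.names = NULL)
  for (sn in step_names) {
    out[[paste0(sn, "_votes_for")]] <- vapply(detail, function(d) {
      if (sn %in% names(d$step_results)) d$step_results[[sn]]$votes_for else NA_integer_
    }, integer(1))
    out[[paste0(sn, "_n_evaluable")]] <- vapply(detail, function(d) {
      if (sn %in% names(d$step_results)) d$step_results[[sn]]$n_evaluable else NA_integer_
    }, integer(1))
  }
  out$flags <- vapply(detail, function(d) paste(d$flags, collapse = ";"), character(1))
  attr(out, "detail") <- detail
  class(out) <- c("reo_classification", "data.frame")
  out
}

#' @export
print.reo_classification <- function(x, ...) {
  cat("REO panel classification of", nrow(x), "samples\n")
  print(table(factor(x$final_label)))
  flagged <- sum(nzchar(x$flags))
  if (flagged) cat(flagged, "sample(s) carry flags\n")
  invisible(x)
}

#' Predict method for REO panels
#'
#' @param object An [reo_panel].
#' @param newdata Genes-by-samples numeric matrix.
#' @param type `"label"` for a named character vector of final labels,
#'   `"detail"` for the full [classify_matrix] result.
#' @param ... Passed to [classify_matrix].
#' @return See `type`.
#' @export
predict.reo_panel <- function(object, newdata, type = c("label", "detail"), ...) {
  type <- match.arg(type)
  res <- classify_matrix(newdata, object, ...)
  if (type == "label") stats::setNames(res$final_label, res$sample_id) else res
}

#' Apparent accuracy, sensitivity and specificity of predictions
#'
#' Concordance of predicted with pathological labels, expressed as
#' `S / N x 100` where `S` counts concordant samples. "Apparent" marks that
#' pathological diagnosis is itself imperfect ground truth. Sensitivity is the
#' concordance restricted to samples whose true label is `positive_label`,
#' specificity the concordance on the remaining samples. `UNDETERMINED`
#' predictions count as incorrect; an empty stratum yields `NA` rather than 0.
#'
#' @param predicted Named character vector of predicted labels, or an
#'   `reo_classification` (its `final_label` column is used).
#' @param truth Named character vector of reference labels.
#' @param positive_label Label defining the sensitivity stratum.
#' @param label_map Optional named vector coarsening `truth` (e.g. mapping
#'   fine subtypes onto NE / non-NE) before comparison.
#' @return List of class `reo_accuracy` with `accuracy`, `sensitivity`,
#'   `specificity` (percentages), and the underlying counts.
#' @examples
#' evaluate_predictions(c(a = "NE", b = "NE", c = "non-NE"),
#'                      c(a = "NE", b = "non-NE", c = "non-NE"), "NE")
#' @export
evaluate_predictions <- function(predicted, truth, positive_label,
                                 label_map = NULL) {
  if (inherits(predicted, "reo_classification")) {
    predicted <- stats::setNames(predicted$final_label, predicted$sample_id)
  }
  truth <- match_labels(truth, names(predicted))
  if (!is.null(label_map)) {
    mapped <- label_map[truth]
    bad <- is.na(mapped)
    if (any(bad)) stop("label_map does not cover label(s): ",
                       paste(unique(truth[bad]), collapse = ", "))
    truth <- stats::setNames(as.character(mapped), names(truth))
  }
  correct <- predicted == truth
  pos <- truth == positive_label
  pct <- function(s, n) if (n == 0L) NA_real_ else s / n * 100
  out <- list(
    n = length(correct), s = sum(correct),
    accuracy = pct(sum(correct), length(correct)),
    n_positive = sum(pos), s_positive = sum(correct & pos),
    sensitivity = pct(sum(correct & pos), sum(pos)),
    n_negative = sum(!pos), s_negative = sum(correct & !pos),
    specificity = pct(sum(correct & !pos), sum(!pos)),
    positive_label = positive_label)
  class(out) <- "reo_accuracy"
  out
}

#' @export
print.reo_accuracy <- function(x, ...) {
  fmt <- function(v, s, n) if (is.na(v)) "NA (empty stratum)" else
    sprintf("%.2f%% (%d/%d)", v, s, n)
  cat("apparent accuracy:   ", fmt(x$accuracy, x$s, x$n), "\n", sep = "")
  cat("apparent sensitivity (", x$positive_label, "): ",
      fmt(x$sensitivity, x$s_positive, x$n_positive), "\n", sep = "")
  cat("apparent specificity: ", fmt(x$specificity, x$s_negative, x$n_negative),
      "\n", sep = "")
  invisible(x)
}

#' Write classification results to TSV (and optionally JSON detail)
#'
#' @param results An `reo_classification`.
#' @param path Output TSV path.
#' @param json_path Optional path for full per-step JSON detail.
#' @export
write_classification <- function(results, path, json_path = NULL) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(attr(results, "detail"), json_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
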