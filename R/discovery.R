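#' Discovery pipeline configuration
#'
#' Thresholds controlling signature discovery. Defaults follow the published
#' procedure: differentially expressed genes at Benjamini-Hochberg FDR < 5%,
#' the 1,000 DE genes with the largest fold changes as candidates, and
#' reversed gene pairs retained at Fisher-exact FDR < 5%.
#'
#' @param de_fdr_threshold FDR cutoff for DE genes (default 0.05).
#' @param n_candidates Number of top-fold-change DE genes kept (default 1000).
#' @param pair_fdr_threshold FDR cutoff for reversed pairs (default 0.05).
#' @param log_scale Logical; `TRUE` (default) declares the input matrix to be
#'   on a log-like scale, so log2 fold change is the difference of group
#'   means. Never auto-guessed.
#' @param max_pairs Combinatorial guard: mining more than this many pairs
#'   requires `allow_large = TRUE`.
#' @param allow_large Override the pair-count guard.
#' @return List of class `discovery_config`.
#' @export
discovery_config <- function(de_fdr_threshold = 0.05, n_candidates = 1000L,
                             pair_fdr_threshold = 0.05, log_scale = TRUE,
                             max_pairs = 1e7, allow_large = FALSE) {
  stopifnot(de_fdr_threshold > 0, de_fdr_threshold <= 1,
            pair_fdr_threshold > 0, pair_fdr_threshold <= 1,
            n_candidates >= 2)
  structure(list(de_fdr_threshold = de_fdr_threshold,
                 n_candidates = as.integer(n_candidates),
                 pair_fdr_threshold = pair_fdr_threshold,
                 log_scale = isTRUE(log_scale),
                 max_pairs = max_pairs, allow_large = isTRUE(allow_large)),
            class = "discovery_config")
}

# Split sample ids into positive/negative groups from a two-level label vector.
two_groups <- function(mat, labels, positive_label) {
  labels <- match_labels(labels, colnames(mat))
  lev <- unique(labels)
  if (!positive_label %in% lev) {
    stop("positive_label '", positive_label, "' absent from labels")
  }
  if (length(lev) != 2L) {
    stop("exactly two label groups required, found: ", paste(lev, collapse = ", "))
  }
  list(pos = names(labels)[labels == positive_label],
       neg = names(labels)[labels != positive_label],
       negative_label = setdiff(lev, positive_label))
}

#' Differentially expressed genes by pooled-variance t test
#'
#' Two-sample Student's t test (pooled variance) per gene between the
#' positive- and negative-label groups, with Benjamini-Hochberg adjustment.
#' Genes with zero variance in both groups (t undefined) or fewer than two
#' non-missing values in a group are excluded; their count is reported via
#' `message()`.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param labels Named two-level label vector covering the samples.
#' @param positive_label Label of the positive group.
#' @param config A [discovery_config].
#' @return data.frame with `gene_id`, `t_statistic`, `p_value`, `fdr`,
#'   `log2_fc` (positive-minus-negative on log2 scale), `fold_change` (linear)
#'   and `significant`, ordered by `|log2_fc|` descending within the
#'   significant genes first.
#' @export
find_de_genes <- function(mat, labels, positive_label,
                          config = discovery_config()) {
  validate_expression_matrix(mat)
  g <- two_groups(mat, labels, positive_label)
  if (length(g$pos) < 2L || length(g$neg) < 2L) {
    stop("each group needs at least two samples")
  }
  x1 <- mat[, g$pos, drop = FALSE]
  x2 <- mat[, g$neg, drop = FALSE]
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- (rowSums(x1^2, na.rm = TRUE) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(x2^2, na.rm = TRUE) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0)  # guard tiny negative values from cancellation
  v2 <- pmax(v2, 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  usable <- n1 >= 2 & n2 >= 2 & sp2 > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) excluded (zero variance or insufficient data)")
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  keep <- which(usable)
  out <- data.frame(
    gene_id = rownames(mat)[keep],
    t_statistic = tstat[keep],
    p_value = p[keep],
    fdr = stats::p.adjust(p[keep], method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$log2_fc <- if (config$log_scale) (m1 - m2)[keep] else
    log2(m1[keep] / m2[keep])
  out$fold_change <- 2^out$log2_fc
  out$significant <- out$fdr < config$de_fdr_threshold
  out[order(-out$significant, -abs(out$log2_fc), out$fdr, out$gene_id), ,
      drop = FALSE]
}

#' Select top candidate genes by fold change
#'
#' Keeps the `n` FDR-significant DE genes with the largest absolute log2 fold
#' changes; ties at the cutoff break by smaller FDR, then by gene-ID order.
#' If fewer significant genes exist, all are returned with a warning.
#'
#' @param de_genes Result of [find_de_genes].
#' @param n Number of candidates (default 1000).
#' @return Character vector of gene IDs.
#' @export
select_candidates <- function(de_genes, n = 1000L) {
  sig <- de_genes[de_genes$significant, , drop = FALSE]
  sig <- sig[order(-abs(sig$log2_fc), sig$fdr, sig$gene_id), , drop = FALSE]
  if (nrow(sig) < n) {
    warning("only ", nrow(sig), " significant genes available (requested ", n, ")")
    return(sig$gene_id)
  }
  sig$gene_id[seq_len(n)]
}

# Accumulate GT counts and evaluable counts for all gene pairs of `sub`
# (genes x samples). Returns list(gt = matrix, ev = matrix), both
# genes x genes, entry [i, j] = count of samples with value(i) > value(j).
pair_pattern_counts <- function(sub) {
  p <- nrow(sub)
  gt <- matrix(0L, p, p)
  ev <- matrix(0L, p, p)
  for (s in seq_len(ncol(sub))) {
    x <- sub[, s]
    cmp <- outer(x, x, ">")
    ok <- !is.na(cmp)
    gt <- gt + (cmp & ok)
    ev <- ev + ok
  }
  dimnames(gt) <- dimnames(ev) <- list(rownames(sub), rownames(sub))
  list(gt = gt, ev = ev)
}

# Two-sided Fisher exact p for tables given as vectors, memoized on the table.
fisher_p_vec <- function(a, b, c, d) {
  cache <- new.env(parent = emptyenv())
  vapply(seq_along(a), function(i) {
    key <- paste(a[i], b[i], c[i], d[i])
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2L))$p.value
    cache[[key]] <- p
    p
  }, numeric(1))
}

#' Mine significantly reversed gene pairs
#'
#' For every unordered pair of candidate genes, tests with a two-sided Fisher
#' exact test whether the frequency of the `gene_a > gene_b` pattern differs
#' between the two groups (ties count in the `<=` branch; samples missing
#' either gene are excluded from that pair's table). P values are
#' Benjamini-Hochberg adjusted across all tested pairs and pairs with
#' FDR below the threshold are kept, oriented so that the `GT` pattern is the
#' more frequent one in the positive-label group.
#'
#' @inheritParams find_de_genes
#' @param candidates Character vector of candidate gene IDs (must be rows of
#'   `mat`).
#' @return data.frame with `gene_a`, `gene_b`, per-group `GT` counts and
#'   frequencies, `fisher_p` and `fdr`, one row per retained pair.
#' @export
mine_reversed_pairs <- function(mat, labels, candidates, positive_label,
                                config = discovery_config()) {
  validate_expression_matrix(mat)
  miss <- setdiff(candidates, rownames(mat))
  if (length(miss)) stop("candidate gene(s) absent from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  n_pairs <- choose(length(candidates), 2)
  if (n_pairs > config$max_pairs && !config$allow_large) {
    stop(format(n_pairs, big.mark = ","), " candidate pairs exceed the guard (",
         format(config$max_pairs, scientific = FALSE),
         "); set allow_large = TRUE in the config to override")
  }
  g <- two_groups(mat, labels, positive_label)
  cp <- pair_pattern_counts(mat[candidates, g$pos, drop = FALSE])
  cn <- pair_pattern_counts(mat[candidates, g$neg, drop = FALSE])
  ut <- upper.tri(cp$gt)
  idx <- which(ut, arr.ind = TRUE)
  ga <- candidates[idx[, 1]]
  gb <- candidates[idx[, 2]]
  gt_pos <- cp$gt[ut]; ev_pos <- cp$ev[ut]
  gt_neg <- cn$gt[ut]; ev_neg <- cn$ev[ut]
  p <- fisher_p_vec(gt_pos, ev_pos - gt_pos, gt_neg, ev_neg - gt_neg)
  fdr <- stats::p.adjust(p, method = "BH")
  keep <- which(fdr < config$pair_fdr_threshold)
  if (!length(keep)) {
    res <- data.frame(gene_a = character(0), gene_b = character(0),
                      gt_pos = integer(0), n_pos = integer(0),
                      gt_neg = integer(0), n_neg = integer(0),
                      freq_gt_pos = numeric(0), freq_gt_neg = numeric(0),
                      fisher_p = numeric(0), fdr = numeric(0))
    attr(res, "n_tested") <- n_pairs
    return(res)
  }
  res <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                    gt_pos = gt_pos[keep], n_pos = ev_pos[keep],
                    gt_neg = gt_neg[keep], n_neg = ev_neg[keep],
                    fisher_p = p[keep], fdr = fdr[keep],
                    stringsAsFactors = FALSE)
  # orient so the GT pattern is the positive-group pattern
  fp <- res$gt_pos / res$n_pos
  fn <- res$gt_neg / res$n_neg
  flip <- !is.na(fp) & !is.na(fn) & fp < fn
  if (any(flip)) {
    tmp_a <- res$gene_a[flip]
    res$gene_a[flip] <- res$gene_b[flip]
    res$gene_b[flip] <- tmp_a
    res$gt_pos[flip] <- res$n_pos[flip] - res$gt_pos[flip]
    res$gt_neg[flip] <- res$n_neg[flip] - res$gt_neg[flip]
  }
  res$freq_gt_pos <- res$gt_pos / res$n_pos
  res$freq_gt_neg <- res$gt_neg / res$n_neg
  res <- res[, c("gene_a", "gene_b", "gt_pos", "n_pos", "gt_neg", "n_neg",
                 "freq_gt_pos", "freq_gt_neg", "fisher_p", "fdr")]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_pairs
  res
}

#' Apparent accuracy of single gene pairs
#'
#' A sample is predicted positive exactly when its pattern is
#' `gene_a > gene_b`; a missing pattern never predicts positive. The apparent
#' accuracy is `S / N x 100` with `S` the samples (over both groups) whose
#' prediction matches their label and `N` all samples.
#'
#' @inheritParams find_de_genes
#' @param pairs data.frame with columns `gene_a`, `gene_b` (e.g. the result
#'   of [mine_reversed_pairs]).
#' @return Numeric vector of percentages, one per pair.
#' @export
pair_apparent_accuracy <- function(pairs, mat, labels, positive_label) {
  g <- two_groups(mat, labels, positive_label)
  n <- length(g$pos) + length(g$neg)
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- mat[pairs$gene_a[i], ]
    b <- mat[pairs$gene_b[i], ]
    gt <- !is.na(a) & !is.na(b) & a > b
    s <- sum(gt[g$pos]) + sum(!gt[g$neg])
    s / n * 100
  }, numeric(1))
}

#' Rank-difference score of gene pairs
#'
#' Within each sample, genes of the `rank_universe` are ranked (fractional
#' ranks for ties) and the absolute rank difference of the pair is taken,
#' flooring exact zeroes at 0.5 so the geometric mean is defined. The score is
#' the product of the two groups' geometric means of these differences; larger
#' scores mean the pair's ordering is backed by a wider expression gap and is
#' therefore more robust. Computed from ranks only, the score is invariant to
#' any within-sample order-preserving transformation.
#'
#' @inheritParams pair_apparent_accuracy
#' @param rank_universe Genes over which within-sample ranks are computed
#'   (default: all rows of `mat`; discovery uses the candidate set).
#' @return Numeric vector of scores, one per pair.
#' @export
pair_rank_difference <- function(pairs, mat, labels, positive_label,
                                 rank_universe = rownames(mat)) {
  g <- two_groups(mat, labels, positive_label)
  sub <- mat[rank_universe, , drop = FALSE]
  ranks <- apply(sub, 2, rank, ties.method = "average", na.last = "keep")
  rownames(ranks) <- rank_universe
  geo <- function(d) {
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    exp(mean(log(pmax(d, 0.5))))
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    d <- abs(ranks[pairs$gene_a[i], ] - ranks[pairs$gene_b[i], ])
    geo(d[g$pos]) * geo(d[g$neg])
  }, numeric(1))
}

#' Greedy de-redundant pair selection
#'
#' Reduces a scored set of reversed pairs to a signature in which every gene
#' appears in at most one pair. Pairs are ranked by apparent accuracy
#' (descending), then rank-difference score (descending), then lexicographic
#' gene IDs, and accepted greedily when neither gene has been used. The total
#' order makes the result deterministic and independent of input order.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `apparent_accuracy`,
#'   `rank_diff_score` (extra columns are carried through).
#' @param name,positive_label,negative_label Passed to [reo_signature].
#' @return An [reo_signature]; the selected rows (with scores) are kept in the
#'   `"selected_pairs"` attribute.
#' @export
deredundant_select <- function(pairs, name, positive_label, negative_label) {
  if (nrow(pairs) == 0L) stop("no pairs to select from (empty input)")
  ord <- order(-pairs$apparent_accuracy, -pairs$rank_diff_score,
               pairs$gene_a, pairs$gene_b)
  pairs <- pairs[ord, , drop = FALSE]
  used <- character(0)
  take <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (!(pairs$gene_a[i] %in% used) && !(pairs$gene_b[i] %in% used)) {
      take[i] <- TRUE
      used <- c(used, pairs$gene_a[i], pairs$gene_b[i])
    }
  }
  sel <- pairs[take, , drop = FALSE]
  sig <- reo_signature(sel[, c("gene_a", "gene_b")], name = name,
                       positive_label = positive_label,
                       negative_label = negative_label)
  attr(sig, "selected_pairs") <- sel
  sig
}

#' Build one binary REO signature from labelled expression data
#'
#' Runs the full discovery chain: pooled-t DE genes (BH FDR), top-fold-change
#' candidate selection, Fisher-exact reversed-pair mining (BH FDR),
#' apparent-accuracy and rank-difference scoring, and greedy de-redundant
#' selection. The returned signature carries a training report (apparent
#' sensitivity/specificity of the majority vote on the training samples) in
#' its `"training"` attribute.
#'
#' @inheritParams find_de_genes
#' @param name Signature name.
#' @return An [reo_signature].
#' @export
build_signature <- function(mat, labels, positive_label,
                            config = discovery_config(),
                            name = paste0(positive_label, "-signature")) {
  g <- two_groups(mat, labels, positive_label)
  de <- find_de_genes(mat, labels, positive_label, config)
  cand <- select_candidates(de, config$n_candidates)
  if (length(cand) < 2L) {
    stop("signature discovery failed: fewer than two FDR-significant DE genes (",
         nrow(de), " genes tested)")
  }
  mined <- mine_reversed_pairs(mat, labels, cand, positive_label, config)
  if (nrow(mined) == 0L) {
    stop("signature discovery failed: no reversed pairs at FDR < ",
         config$pair_fdr_threshold, " (", attr(mined, "n_tested"),
         " pairs tested among ", length(cand), " candidates)")
  }
  mined$apparent_accuracy <- pair_apparent_accuracy(mined, mat, labels, positive_label)
  mined$rank_diff_score <- pair_rank_difference(mined, mat, labels, positive_label,
                                                rank_universe = cand)
  sig <- deredundant_select(mined, name = name,
                            positive_label = positive_label,
                            negative_label = g$negative_label)
  pred <- vapply(colnames(mat), function(s) {
    score_signature(mat[, s], sig)$call
  }, character(1))
  truth <- match_labels(labels, colnames(mat))
  truth <- stats::setNames(ifelse(truth == positive_label, positive_label,
                                  g$negative_label), names(truth))
  attr(sig, "training") <- evaluate_predictions(pred, truth, positive_label)
  sig
}

#' Train a hierarchical lung-subtype panel
#'
#' Builds the three binary signatures of the step-wise decision tree from a
#' five-subtype training set (SCLC, LCNEC, CARCI, ADC, SCC):
#' step 1 separates NE (SCLC + LCNEC + CARCI) from non-NE (ADC + SCC) on all
#' samples; step 2 separates CARCI from the other NE subtypes on the NE
#' samples; step 3 separates SCLC from LCNEC. With `cluster_filter = TRUE`,
#' samples whose consensus-cluster assignment is discordant with their
#' pathological side are removed before each step (see [flag_discordant]),
#' cleaning mislabelled training samples at the cost of extra computation.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param labels Named vector with values in
#'   `c("SCLC", "LCNEC", "CARCI", "ADC", "SCC")`.
#' @param config A [discovery_config].
#' @param cluster_filter Logical; apply consensus-clustering sample filtering
#'   before each step.
#' @param cluster_config A [consensus_config] used when filtering.
#' @return An `reo_panel` with a `training` element recording per-step
#'   apparent accuracy and any removed samples.
#' @seealso [predict.reo_panel], [builtin_panel]
#' @export
train_panel <- function(mat, labels, config = discovery_config(),
                        cluster_filter = FALSE,
                        cluster_config = consensus_config(k_range = 2L,
                                                          n_resamples = 100L)) {
  validate_expression_matrix(mat)
  labels <- match_labels(labels, colnames(mat))
  vocab <- c("SCLC", "LCNEC", "CARCI", "ADC", "SCC")
  bad <- setdiff(unique(labels), vocab)
  if (length(bad)) stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  ne_map <- c(SCLC = "NE", LCNEC = "NE", CARCI = "NE",
              ADC = "non-NE", SCC = "non-NE")
  removed <- list()

  filter_step <- function(samples, binary) {
    # binary: named vector sample -> side for this step
    if (!cluster_filter) return(samples)
    cc <- consensus_cluster(mat[, samples, drop = FALSE], cluster_config)
    disc <- flag_discordant(cc$assignment, binary[samples])
    removed[[length(removed) + 1L]] <<- disc
    setdiff(samples, disc)
  }

  make_step <- function(samples, binary, positive, name) {
    counts <- table(binary[samples])
    if (length(counts) < 2L || any(counts < 4L)) {
      stop("step '", name, "' needs at least 4 samples per group (have ",
           paste(names(counts), counts, sep = "=", collapse = ", "), ")")
    }
    build_signature(mat[, samples, drop = FALSE], binary[samples], positive,
                    config = config, name = name)
  }

  all_samples <- colnames(mat)
  step1_lab <- stats::setNames(ne_map[labels], names(labels))
  s1_samples <- filter_step(all_samples, step1_lab)
  sig_ne <- make_step(s1_samples, step1_lab, "NE", "NE-signature")

  ne_samples <- names(labels)[labels %in% c("SCLC", "LCNEC", "CARCI")]
  step2_lab <- stats::setNames(ifelse(labels[ne_samples] == "CARCI",
                                      "CARCI", "non-CARCI"), ne_samples)
  s2_samples <- filter_step(ne_samples, step2_lab)
  sig_carci <- make_step(s2_samples, step2_lab, "CARCI", "CARCI-signature")

  sl_samples <- names(labels)[labels %in% c("SCLC", "LCNEC")]
  step3_lab <- labels[sl_samples]
  s3_samples <- filter_step(sl_samples, step3_lab)
  sig_sclc <- make_step(s3_samples, step3_lab, "SCLC", "SCLC-signature")

  panel <- reo_panel(
    steps = list(sig_ne, sig_carci, sig_sclc),
    routing = list(
      list(on_positive = "step:2", on_negative = "label:non-NE"),
      list(on_positive = "label:CARCI", on_negative = "step:3"),
      list(on_positive = "label:SCLC", on_negative = "label:LCNEC")),
    name = "trained NE-subtype panel",
    terminal_labels = c("non-NE", "CARCI", "SCLC", "LCNEC"))
  panel$training <- list(
    steps = stats::setNames(
      lapply(list(sig_ne, sig_carci, sig_sclc), attr, "training"),
      c("NE-signature", "CARCI-signature", "SCLC-signature")),
    removed_samples = removed)
  panel
}

#' Write the per-pair discovery report of a trained panel
#'
#' One TSV row per retained pair with its per-group GT frequencies, Fisher
#' p value, FDR, apparent accuracy and rank-difference score.
#'
#' @param panel A trained `reo_panel`.
#' @param path Output TSV path.
#' @export
write_pair_report <- function(panel, path) {
  rows <- lapply(panel$steps, function(s) {
    sel <- attr(s, "selected_pairs")
    if (is.null(sel)) return(NULL)
    cbind(signature = s$name, sel)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) stop("panel carries no discovery scores (not trained?)")
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
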