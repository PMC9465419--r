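#' Consensus clustering configuration
#'
#' @param k_range Candidate cluster numbers (default `2:10`).
#' @param n_resamples Number of subsampling repetitions (default 1000).
#' @param sample_fraction Fraction of samples drawn per repetition
#'   (default 0.8).
#' @param n_top_genes Number of most-variable genes used for clustering
#'   (default 1000; capped at the gene count).
#' @param pac_bounds Lower and upper consensus bounds of the ambiguous band
#'   used by the PAC (proportion of ambiguous clustering) criterion for
#'   choosing `k` (default `c(0.1, 0.9)`): the chosen `k` minimizes the
#'   fraction of sample pairs whose consensus falls strictly inside the band,
#'   i.e. it seeks the sharpest-stepped consensus CDF.
#' @param seed Optional integer seed making the resampling reproducible.
#' @return List of class `consensus_config`.
#' @export
consensus_config <- function(k_range = 2:10, n_resamples = 1000L,
                             sample_fraction = 0.8, n_top_genes = 1000L,
                             pac_bounds = c(0.1, 0.9), seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2L), sample_fraction > 0, sample_fraction <= 1,
            n_resamples >= 1L, length(pac_bounds) == 2L,
            pac_bounds[1] < pac_bounds[2])
  structure(list(k_range = k_range, n_resamples = as.integer(n_resamples),
                 sample_fraction = sample_fraction,
                 n_top_genes = as.integer(n_top_genes),
                 pac_bounds = pac_bounds, seed = seed),
            class = "consensus_config")
}

#' Most variable genes across samples
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param n Number of genes to return.
#' @return Character vector: the `n` genes with the largest variance across
#'   samples (ties broken by gene-ID order).
#' @export
top_variable_genes <- function(mat, n) {
  validate_expression_matrix(mat)
  if (n > nrow(mat)) stop("n exceeds the number of genes")
  m <- rowMeans(mat, na.rm = TRUE)
  nn <- rowSums(!is.na(mat))
  v <- (rowSums(mat^2, na.rm = TRUE) - nn * m^2) / pmax(nn - 1, 1)
  v[nn < 2] <- 0
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord[seq_len(n)]]
}

ward_cut <- function(d, k) {
  stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
}

pearson_dist <- function(x) {
  # samples in columns; 1 - Pearson correlation between sample profiles
  stats::as.dist(1 - stats::cor(x, use = "pairwise.complete.obs"))
}

#' Consensus clustering of samples
#'
#' Resampled hierarchical clustering: in each repetition a fraction of the
#' samples is drawn, clustered with Ward linkage on Pearson-correlation
#' distance over the most variable genes, and cut at each candidate `k`. The
#' consensus index of a sample pair at a given `k` is the fraction of
#' co-drawn repetitions in which the pair co-clustered. The number of
#' clusters is chosen as the `k` whose consensus CDF is closest to a pure
#' step function, measured by the PAC criterion (smallest proportion of
#' pairs with ambiguous consensus, ties to the smaller `k`); the area under
#' the CDF and its relative gain per `k` are reported alongside. The final
#' hard assignment is a Ward cut of `1 - consensus` at the chosen `k`.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param config A [consensus_config].
#' @return List of class `consensus_result`: `consensus` (one sample-by-sample
#'   matrix per `k`), `cdf_area`, `delta_area`, `chosen_k`, `assignment`
#'   (named integer vector) and the `config`.
#' @export
consensus_cluster <- function(mat, config = consensus_config()) {
  validate_expression_matrix(mat)
  ns <- ncol(mat)
  if (ns < 2L * max(config$k_range)) {
    stop("need at least ", 2L * max(config$k_range), " samples for k up to ",
         max(config$k_range))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  genes <- top_variable_genes(mat, min(config$n_top_genes, nrow(mat)))
  sub <- mat[genes, , drop = FALSE]
  m <- max(2L, round(config$sample_fraction * ns))
  kr <- config$k_range
  co <- lapply(kr, function(k) matrix(0, ns, ns))
  names(co) <- as.character(kr)
  together <- matrix(0, ns, ns)
  for (rep in seq_len(config$n_resamples)) {
    take <- sort(sample.int(ns, m))
    together[take, take] <- together[take, take] + 1
    hc <- stats::hclust(pearson_dist(sub[, take, drop = FALSE]),
                        method = "ward.D2")
    for (ki in seq_along(kr)) {
      cl <- stats::cutree(hc, k = min(kr[ki], m))
      same <- outer(cl, cl, "==")
      co[[ki]][take, take] <- co[[ki]][take, take] + same
    }
  }
  if (any(together[upper.tri(together)] == 0)) {
    stop("some sample pairs were never co-drawn; increase n_resamples or ",
         "sample_fraction")
  }
  consensus <- lapply(co, function(cm) {
    out <- cm / together
    diag(out) <- 1
    dimnames(out) <- list(colnames(mat), colnames(mat))
    out
  })
  cdf_area <- vapply(consensus, function(cm) {
    v <- sort(cm[upper.tri(cm)])
    # area under the empirical CDF over [0, 1]
    grid <- c(v, 1)
    sum(diff(c(0, grid)) * c(0, seq_along(v)) / length(v))
  }, numeric(1))
  delta <- numeric(length(kr))
  delta[1] <- cdf_area[1]
  if (length(kr) > 1) {
    delta[-1] <- diff(cdf_area) / utils::head(cdf_area, -1)
  }
  pac <- vapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    mean(v > config$pac_bounds[1] & v < config$pac_bounds[2])
  }, numeric(1))
  chosen <- kr[which.min(pac)]
  assignment <- ward_cut(stats::as.dist(1 - consensus[[as.character(chosen)]]),
                         chosen)
  names(assignment) <- colnames(mat)
  structure(list(consensus = consensus, cdf_area = cdf_area,
                 delta_area = stats::setNames(delta, as.character(kr)),
                 pac = stats::setNames(pac, as.character(kr)),
                 chosen_k = chosen, assignment = assignment, config = config),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering of", length(x$assignment), "samples; chosen k =",
      x$chosen_k, "\n")
  print(table(x$assignment))
  invisible(x)
}

#' Flag samples discordant with their pathological side
#'
#' For a binary step, each of the two consensus clusters is named after the
#' majority pathological side among its members; a sample is discordant when
#' its own side differs from its cluster's name. An exact 50/50 side split
#' within a cluster is ambiguous and raises an error rather than choosing
#' silently.
#'
#' @param assignment Named integer vector of cluster memberships with exactly
#'   two clusters (e.g. `consensus_cluster(...)$assignment` at `k = 2`), or a
#'   `consensus_result`.
#' @param sides Named character vector mapping each sample to its
#'   pathological side for this step (two levels).
#' @return Character vector of discordant sample IDs (possibly empty).
#' @export
flag_discordant <- function(assignment, sides) {
  if (inherits(assignment, "consensus_result")) {
    assignment <- assignment$assignment
  }
  if (length(unique(assignment)) != 2L) {
    stop("discordance flagging requires exactly two clusters (binary step)")
  }
  sides <- match_labels(sides, names(assignment))
  cluster_side <- vapply(split(sides, assignment), function(s) {
    tab <- sort(table(s), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      stop("cluster has an exact 50/50 label split; cannot map clusters to sides")
    }
    names(tab)[1]
  }, character(1))
  names(assignment)[sides != cluster_side[as.character(assignment)]]
}
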