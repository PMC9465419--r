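#' Simulation configuration for planted-REO expression data
#'
#' Describes a synthetic genes-by-samples dataset with subtype-specific
#' reversed gene pairs planted on top of i.i.d. Gaussian background noise.
#' Defaults emulate the five-subtype training regime of the diagnostic
#' problem: sample counts matching a surgical lung-cancer cohort
#' (21 SCLC, 56 LCNEC, 24 CARCI, 85 ADC, 61 SCC), log2-intensity-like values
#' around a baseline of 8, and 30 planted pairs per hierarchy step at effect
#' size 3 (in noise-SD units).
#'
#' With five subtypes, pairs are planted for three binary steps
#' (NE vs non-NE; CARCI vs other NE; SCLC vs LCNEC): in a step's positive
#' group `gene_a` has mean `mu0 + effect_size * noise_sd` and `gene_b`
#' `mu0 - effect_size * noise_sd`, reversed in the step's negative group, and
#' baseline elsewhere. Supplying exactly two named sample counts instead
#' yields a two-group design with a single planted step whose positive class
#' is the first name. Planted pairs occupy fixed gene indices determined by
#' the configuration alone, so datasets simulated from the same configuration
#' under different seeds share their ground truth.
#'
#' @param n_genes Total number of genes (planted plus background).
#' @param n_samples Named integer vector of samples per subtype: either the
#'   five subtypes `SCLC, LCNEC, CARCI, ADC, SCC` or exactly two groups.
#' @param n_planted_pairs Pairs planted per step (recycled across steps).
#' @param effect_size Mean offset separating `gene_a` from `gene_b`, in units
#'   of `noise_sd`; 0 plants nothing distinguishable.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param mu0 Baseline mean expression.
#' @param dropout_rate Probability that any value is missing (biopsy/FFPE
#'   emulation).
#' @param label_corruption_rate Fraction of samples whose observed label is
#'   swapped to a random other subtype (the true label is retained in the
#'   ground truth).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples = c(SCLC = 21L, LCNEC = 56L, CARCI = 24L,
                                     ADC = 85L, SCC = 61L),
                       n_planted_pairs = 30L,
                       effect_size = 3, noise_sd = 1, mu0 = 8,
                       dropout_rate = 0, label_corruption_rate = 0) {
  if (is.null(names(n_samples)) || any(!nzchar(names(n_samples)))) {
    stop("n_samples must be a named vector of per-subtype sample counts")
  }
  five <- c("SCLC", "LCNEC", "CARCI", "ADC", "SCC")
  if (length(n_samples) != 2L && !setequal(names(n_samples), five)) {
    stop("n_samples must name either two groups or the five subtypes ",
         paste(five, collapse = ", "))
  }
  stopifnot(effect_size >= 0, noise_sd > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            label_corruption_rate >= 0, label_corruption_rate <= 1)
  steps <- if (length(n_samples) == 2L) 1L else 3L
  n_planted_pairs <- rep_len(as.integer(n_planted_pairs), steps)
  if (2L * sum(n_planted_pairs) > n_genes) {
    stop("planted pairs require ", 2L * sum(n_planted_pairs),
         " genes but n_genes = ", n_genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = n_samples, n_planted_pairs = n_planted_pairs,
                 effect_size = effect_size, noise_sd = noise_sd, mu0 = mu0,
                 dropout_rate = dropout_rate,
                 label_corruption_rate = label_corruption_rate),
            class = "sim_config")
}

# Step definitions (positive/negative label sets) implied by a sim_config.
sim_steps <- function(config) {
  if (length(config$n_samples) == 2L) {
    nm <- names(config$n_samples)
    return(list(list(name = nm[1], positive = nm[1], negative = nm[2],
                     pos_labels = nm[1], neg_labels = nm[2])))
  }
  list(
    list(name = "NE", positive = "NE", negative = "non-NE",
         pos_labels = c("SCLC", "LCNEC", "CARCI"), neg_labels = c("ADC", "SCC")),
    list(name = "CARCI", positive = "CARCI", negative = "non-CARCI",
         pos_labels = "CARCI", neg_labels = c("SCLC", "LCNEC")),
    list(name = "SCLC", positive = "SCLC", negative = "LCNEC",
         pos_labels = "SCLC", neg_labels = "LCNEC"))
}

#' Simulate an expression dataset with planted reversed pairs
#'
#' @param config A [sim_config].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(config, seed)`.
#' @return List of class `reo_simulation`: `matrix` (genes x samples, with
#'   `NA` for dropout), `labels_true`, `labels_observed`, and `truth` holding
#'   the planted pairs per step plus the IDs of label-corrupted samples.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100,
#'   n_samples = c(NE = 10, `non-NE` = 10), n_planted_pairs = 5), seed = 1)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  subtype <- rep(names(config$n_samples), config$n_samples)
  ntot <- length(subtype)
  sample_ids <- sprintf("s%04d", seq_len(ntot))
  names(subtype) <- sample_ids

  steps <- sim_steps(config)
  mu <- matrix(config$mu0, config$n_genes, ntot,
               dimnames = list(gene_ids, sample_ids))
  truth_pairs <- list()
  next_gene <- 1L
  off <- config$effect_size * config$noise_sd
  for (si in seq_along(steps)) {
    st <- steps[[si]]
    np <- config$n_planted_pairs[si]
    ga <- gene_ids[seq(next_gene, by = 2L, length.out = np)]
    gb <- gene_ids[seq(next_gene + 1L, by = 2L, length.out = np)]
    next_gene <- next_gene + 2L * np
    pos <- sample_ids[subtype %in% st$pos_labels]
    neg <- sample_ids[subtype %in% st$neg_labels]
    mu[ga, pos] <- config$mu0 + off
    mu[gb, pos] <- config$mu0 - off
    mu[ga, neg] <- config$mu0 - off
    mu[gb, neg] <- config$mu0 + off
    truth_pairs[[st$name]] <- data.frame(
      gene_a = ga, gene_b = gb, positive_class = st$positive,
      stringsAsFactors = FALSE)
  }

  mat <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                     nrow(mu), ncol(mu))
  dimnames(mat) <- dimnames(mu)
  if (config$dropout_rate > 0) {
    mat[stats::runif(length(mat)) < config$dropout_rate] <- NA_real_
  }

  observed <- subtype
  corrupted <- character(0)
  n_corrupt <- round(config$label_corruption_rate * ntot)
  if (n_corrupt > 0) {
    corrupted <- sample(sample_ids, n_corrupt)
    pool <- unique(subtype)
    observed[corrupted] <- vapply(corrupted, function(s) {
      sample(setdiff(pool, subtype[s]), 1L)
    }, character(1))
  }

  structure(list(matrix = mat, labels_true = subtype,
                 labels_observed = observed,
                 truth = list(pairs = truth_pairs, corrupted_ids = corrupted),
                 config = config, seed = seed),
            class = "reo_simulation")
}

#' @export
print.reo_simulation <- function(x, ...) {
  cat("Synthetic REO dataset:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples (seed", x$seed, ")\n")
  print(table(x$labels_true))
  np <- vapply(x$truth$pairs, nrow, integer(1))
  cat("planted pairs:", paste(names(np), np, sep = "=", collapse = ", "), "\n")
  if (length(x$truth$corrupted_ids)) {
    cat(length(x$truth$corrupted_ids), "sample label(s) corrupted\n")
  }
  invisible(x)
}

#' Randomly mask expression values (degradation model)
#'
#' Missing-at-random dropout emulating RNA degradation in FFPE or low-input
#' biopsy material; used to probe classification stability under feature loss.
#'
#' @param mat Genes-by-samples numeric matrix.
#' @param dropout_rate Probability in `[0, 1)` that each value is masked.
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
degrade_matrix <- function(mat, dropout_rate, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (dropout_rate == 0) return(mat)
  set.seed(seed)
  mat[stats::runif(length(mat)) < dropout_rate] <- NA_real_
  mat
}

#' Archetype samples for a panel (diagnostic fixtures)
#'
#' Builds noiseless-by-construction samples over a panel's genes realizing
#' each terminal label of the decision tree: for every routing path, the
#' pairs of each traversed signature are set to the pattern that path
#' requires, and genes of unvisited signatures are left at the baseline with
#' a tiny jitter so ties cannot occur. Useful as a known-answer fixture for
#' end-to-end classification.
#'
#' @param panel An [reo_panel].
#' @param n_per_label Samples generated per terminal label.
#' @param seed Integer seed for the jitter.
#' @return List with `matrix` and `labels` (the intended terminal labels).
#' @export
simulate_panel_archetypes <- function(panel, n_per_label = 1L, seed = 1L) {
  set.seed(seed)
  genes <- signature_genes(panel)
  paths <- panel_paths(panel)
  cols <- list()
  labels <- character(0)
  for (p in paths) {
    for (r in seq_len(n_per_label)) {
      v <- stats::setNames(stats::rnorm(length(genes), 0, 0.01), genes)
      for (e in p$edges) {
        sig <- panel$steps[[e$step]]
        delta <- if (e$positive) 1 else -1
        v[sig$pairs$gene_a] <- v[sig$pairs$gene_a] + delta
        v[sig$pairs$gene_b] <- v[sig$pairs$gene_b] - delta
      }
      cols[[length(cols) + 1L]] <- v
      labels <- c(labels, p$label)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- sprintf("arch_%02d", seq_len(ncol(mat)))
  names(labels) <- colnames(mat)
  list(matrix = mat, labels = labels)
}

# Enumerate root-to-leaf paths of a panel's decision tree.
panel_paths <- function(panel) {
  out <- list()
  walk <- function(step, edges) {
    for (positive in c(TRUE, FALSE)) {
      tgt <- parse_route(if (positive) panel$routing[[step]]$on_positive
                         else panel$routing[[step]]$on_negative)
      e <- c(edges, list(list(step = step, positive = positive)))
      if (tgt$type == "label") {
        out[[length(out) + 1L]] <<- list(label = tgt$label, edges = e)
      } else {
        walk(tgt$step, e)
      }
    }
  }
  walk(1L, list())
  out
}
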