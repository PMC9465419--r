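# Shared fixtures and independent oracles for the test suite.

# Toy signature over disjoint synthetic genes.
toy_signature <- function(n_pairs = 5, positive = "POS", negative = "NEG",
                          name = "toy") {
  reo_signature(data.frame(gene_a = sprintf("A%02d", seq_len(n_pairs)),
                           gene_b = sprintf("B%02d", seq_len(n_pairs))),
                name = name, positive_label = positive, negative_label = negative)
}

# Sample values realizing a given REO pattern vector ("GT"/"LE"/"TIE"/"MISSING")
# for a signature whose pairs use disjoint genes.
values_for_pattern <- function(sig, pattern) {
  stopifnot(length(pattern) == nrow(sig$pairs))
  v <- numeric(0)
  for (i in seq_along(pattern)) {
    a <- sig$pairs$gene_a[i]
    b <- sig$pairs$gene_b[i]
    v[c(a, b)] <- switch(pattern[i],
                         GT = c(2, 1),
                         LE = c(1, 2),
                         TIE = c(1, 1),
                         MISSING = c(NA_real_, 1))
  }
  v
}

# Brute-force recount of the majority rule, independent of score_signature.
majority_oracle <- function(pattern, positive, negative) {
  evaluable <- sum(pattern != "MISSING")
  votes_for <- sum(pattern == "GT")
  if (evaluable == 0) return("ABSTAIN")
  if (votes_for > evaluable / 2) positive else negative
}

# Independent two-sided Fisher exact p via explicit hypergeometric sums:
# sum of all point probabilities not exceeding the observed one (with the
# customary 1e-7 relative slack for float ties).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(x, m, n, k)
  sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Random strictly increasing transform applied to one sample's values:
# order-preserving remap of the sorted unique values onto sorted positive
# increments, composed with a random affine map.
random_monotone <- function(x) {
  ux <- sort(unique(x[!is.na(x)]))
  y <- cumsum(stats::rexp(length(ux))) * stats::runif(1, 0.1, 10) +
    stats::rnorm(1, sd = 5)
  out <- y[match(x, ux)]
  names(out) <- names(x)
  out
}

# Apply the coarse NE/non-NE panel vocabulary to fine subtype labels.
panel_truth_map <- c(SCLC = "SCLC", LCNEC = "LCNEC", CARCI = "CARCI",
                     ADC = "non-NE", SCC = "non-NE")

# Small deterministic labelled dataset with planted separation, used where a
# full simulation run would be overkill.
tiny_two_group <- function(seed = 1, n_genes = 60, n_per_group = 10,
                           n_planted = 5, effect = 4) {
  simulate_expression(
    sim_config(n_genes = n_genes,
               n_samples = c(POS = n_per_group, NEG = n_per_group),
               n_planted_pairs = n_planted, effect_size = effect),
    seed = seed)
}
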