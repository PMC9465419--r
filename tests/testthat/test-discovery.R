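test_that("pooled t test finds planted genes and controls type I error", {
  # null genes: both groups from the same distribution
  set.seed(101)
  mat <- matrix(rnorm(200 * 40, mean = 10), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("s%03d", 1:40)))
  labs <- setNames(rep(c("A", "B"), each = 20), colnames(mat))
  de <- find_de_genes(mat, labs, "A")
  frac <- mean(de$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(frac, 0.05 + 3 * se)
  expect_equal(sum(de$significant), 0)
  # planted gene with a clear shift reaches significance
  mat["g001", 1:20] <- rnorm(20, 8, 0.5)
  mat["g001", 21:40] <- rnorm(20, 4, 0.5)
  de <- find_de_genes(mat, labs, "A")
  expect_true(de$significant[de$gene_id == "g001"])
  expect_identical(de$gene_id[1], "g001")  # largest |log2 FC| first
  expect_gt(de$log2_fc[de$gene_id == "g001"], 3)
})

test_that("degenerate genes and groups are handled explicitly", {
  mat <- matrix(rnorm(40), 2, 20,
                dimnames = list(c("flat", "ok"), sprintf("s%02d", 1:20)))
  mat["flat", ] <- 5
  labs <- setNames(rep(c("A", "B"), each = 10), colnames(mat))
  expect_message(de <- find_de_genes(mat, labs, "A"), "excluded")
  expect_false("flat" %in% de$gene_id)
  expect_error(find_de_genes(mat[, 1:11], labs[1:11], "A"),
               "at least two samples")
  expect_error(find_de_genes(mat, labs, "C"), "absent from labels")
})

test_that("candidate selection is top-k by |log2 FC| with declared tie-breaks", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   log2_fc = c(3, -4, 2, 2, 1),
                   fdr = c(.01, .01, .02, .01, .04),
                   significant = TRUE)
  expect_identical(select_candidates(de, 3), c("g2", "g1", "g4"))
  expect_warning(all5 <- select_candidates(de, 10), "only 5")
  expect_length(all5, 5)
  de$significant <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_identical(select_candidates(de, 2), c("g2", "g1"))
})

test_that("reversed-pair mining matches the exact hypergeometric oracle", {
  sim <- tiny_two_group(seed = 5, n_genes = 30, n_per_group = 12,
                        n_planted = 4)
  cand <- rownames(sim$matrix)
  mined <- mine_reversed_pairs(sim$matrix, sim$labels_true, cand, "POS",
                               discovery_config(pair_fdr_threshold = 1 - 1e-9))
  expect_gt(nrow(mined), 0)
  for (i in seq_len(nrow(mined))) {
    expect_equal(mined$fisher_p[i],
                 fisher_oracle(mined$gt_pos[i], mined$n_pos[i] - mined$gt_pos[i],
                               mined$gt_neg[i], mined$n_neg[i] - mined$gt_neg[i]),
                 tolerance = 1e-12)
  }
  # orientation: GT always at least as frequent in the positive group
  expect_true(all(mined$freq_gt_pos >= mined$freq_gt_neg))
})

test_that("a perfectly reversed pair is retained, identical margins give p = 1", {
  sim <- tiny_two_group(seed = 6, n_genes = 40, n_per_group = 20,
                        n_planted = 2, effect = 8)
  planted <- sim$truth$pairs[[1]]
  mined <- mine_reversed_pairs(sim$matrix, sim$labels_true,
                               rownames(sim$matrix), "POS")
  key <- paste(mined$gene_a, mined$gene_b)
  expect_true(all(paste(planted$gene_a, planted$gene_b) %in% key))
  hit <- mined[key == paste(planted$gene_a[1], planted$gene_b[1]), ]
  expect_equal(hit$gt_pos, 20)
  expect_equal(hit$gt_neg, 0)
  expect_equal(hit$fisher_p, fisher_oracle(20, 0, 0, 20), tolerance = 1e-12)
  # a pair with identical GT frequency in both groups is never significant
  p_same <- reopanel:::fisher_p_vec(10, 10, 10, 10)
  expect_equal(p_same, 1)
  # combinatorial guard refuses huge requests without the override
  big_cfg <- discovery_config(max_pairs = 10)
  expect_error(mine_reversed_pairs(sim$matrix, sim$labels_true,
                                   rownames(sim$matrix), "POS", big_cfg),
               "allow_large")
})

test_that("apparent accuracy of single pairs follows its definition", {
  sim <- tiny_two_group(seed = 7, n_genes = 20, n_per_group = 20,
                        n_planted = 2, effect = 8)
  planted <- sim$truth$pairs[[1]][1, , drop = FALSE]
  expect_equal(pair_apparent_accuracy(planted, sim$matrix, sim$labels_true,
                                      "POS"), 100)
  # constant predictor on a balanced split scores 50
  mat <- sim$matrix
  mat["g00019", ] <- 10
  mat["g00020", ] <- 1
  const_pair <- data.frame(gene_a = "g00019", gene_b = "g00020")
  expect_equal(pair_apparent_accuracy(const_pair, mat, sim$labels_true, "POS"),
               50)
})

test_that("rank-difference score reproduces hand-computed cases", {
  # 2 genes, 2 samples per group, constant rank difference d over a universe
  # of 9 genes: score = d * d
  mat <- matrix(0, 9, 4, dimnames = list(paste0("g", 1:9), paste0("s", 1:4)))
  for (j in 1:4) mat[, j] <- 1:9
  labs <- setNames(c("P", "P", "N", "N"), colnames(mat))
  pair <- data.frame(gene_a = "g8", gene_b = "g4")  # ranks 8 and 4, d = 4
  expect_equal(pair_rank_difference(pair, mat, labs, "P"), 16)
  # group1 diffs {2, 8}, group2 diffs {4, 4}: geometric means 4 and 4 -> 16
  mat2 <- mat
  # build explicit rank layouts: put g8/g4 at controlled rank distances
  layout <- function(ra, rb) {
    v <- numeric(9)
    others <- setdiff(1:9, c(ra, rb))
    v[c(8, 4)] <- c(ra, rb)
    v[setdiff(1:9, c(8, 4))] <- others
    v
  }
  mat2[, "s1"] <- layout(5, 3)   # |5-3| = 2
  mat2[, "s2"] <- layout(9, 1)   # 8
  mat2[, "s3"] <- layout(6, 2)   # 4
  mat2[, "s4"] <- layout(1, 5)   # 4
  expect_equal(pair_rank_difference(pair, mat2, labs, "P"),
               sqrt(2 * 8) * sqrt(4 * 4))
  # tied expression on both genes contributes the 0.5 floor, not zero
  mat3 <- mat
  mat3["g8", c("s1", "s2")] <- mat3["g4", c("s1", "s2")]
  d_pos <- pair_rank_difference(pair, mat3, labs, "P")
  expect_equal(d_pos, sqrt(0.5 * 0.5) * 4)
  # computed from ranks only: invariant under within-sample monotone maps
  warped <- mat2
  set.seed(3)
  for (j in 1:4) warped[, j] <- random_monotone(mat2[, j])
  expect_equal(pair_rank_difference(pair, warped, labs, "P"),
               pair_rank_difference(pair, mat2, labs, "P"))
})

test_that("de-redundant selection is greedy, deterministic and order-invariant", {
  pairs <- data.frame(
    gene_a = c("A", "A", "D"), gene_b = c("B", "C", "E"),
    apparent_accuracy = c(99, 95, 90), rank_diff_score = c(1, 1, 1),
    stringsAsFactors = FALSE)
  sig <- deredundant_select(pairs, "s", "P", "N")
  expect_identical(sig$pairs$gene_a, c("A", "D"))
  expect_identical(sig$pairs$gene_b, c("B", "E"))
  # equal accuracy broken by rank-difference score
  pairs2 <- data.frame(gene_a = c("A", "A"), gene_b = c("C", "B"),
                       apparent_accuracy = c(99, 99),
                       rank_diff_score = c(9, 16))
  expect_identical(deredundant_select(pairs2, "s", "P", "N")$pairs$gene_b, "B")
  # disjoint pairs are all retained; input order never matters
  pairs3 <- data.frame(gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
                       apparent_accuracy = c(70, 90, 80),
                       rank_diff_score = 1)
  for (ord in list(1:3, 3:1, c(2, 1, 3))) {
    sig3 <- deredundant_select(pairs3[ord, ], "s", "P", "N")
    expect_identical(sort(signature_genes(sig3)), LETTERS[1:6])
    expect_identical(sig3$pairs$gene_a, c("C", "E", "A"))
  }
  expect_error(deredundant_select(pairs3[0, ], "s", "P", "N"), "empty")
})

test_that("signature discovery recovers planted pairs and is deterministic", {
  sim <- simulate_expression(
    sim_config(n_genes = 300, n_samples = c(POS = 30, NEG = 30),
               n_planted_pairs = 15, effect_size = 3), seed = 21)
  suppressWarnings(sig <- build_signature(sim$matrix, sim$labels_true, "POS"))
  planted_genes <- unlist(sim$truth$pairs[[1]][, c("gene_a", "gene_b")])
  recovered <- mean(planted_genes %in% signature_genes(sig))
  expect_gte(recovered, 0.9)
  tr <- attr(sig, "training")
  expect_equal(tr$sensitivity, 100)
  expect_equal(tr$specificity, 100)
  suppressWarnings(sig2 <- build_signature(sim$matrix, sim$labels_true, "POS"))
  expect_equal(sig2, sig)
})

test_that("label permutation yields no discoverable signature", {
  sim <- simulate_expression(
    sim_config(n_genes = 120, n_samples = c(POS = 20, NEG = 20),
               n_planted_pairs = 10, effect_size = 3), seed = 31)
  failures <- 0
  set.seed(99)
  for (r in 1:10) {
    perm <- setNames(sample(sim$labels_true), names(sim$labels_true))
    res <- tryCatch(
      suppressWarnings(build_signature(sim$matrix, perm, "POS")),
      error = function(e) e)
    if (inherits(res, "error")) failures <- failures + 1
  }
  expect_gte(failures, 9)
})

test_that("panel training builds the three-step hierarchy", {
  cfg <- sim_config(n_genes = 400,
                    n_samples = c(SCLC = 12, LCNEC = 12, CARCI = 12,
                                  ADC = 12, SCC = 12),
                    n_planted_pairs = 12, effect_size = 3)
  tr <- simulate_expression(cfg, seed = 41)
  suppressWarnings(panel <- train_panel(tr$matrix, tr$labels_true))
  expect_s3_class(panel, "reo_panel")
  expect_identical(vapply(panel$steps, function(s) s$name, character(1)),
                   c("NE-signature", "CARCI-signature", "SCLC-signature"))
  ho <- simulate_expression(cfg, seed = 42)
  pred <- predict(panel, ho$matrix)
  expect_gte(mean(pred == panel_truth_map[ho$labels_true]), 0.95)
  # refusal on groups that are too small
  few <- c(names(tr$labels_true)[tr$labels_true == "SCLC"][1:3],
           names(tr$labels_true)[tr$labels_true != "SCLC"])
  expect_error(
    suppressWarnings(train_panel(tr$matrix[, few], tr$labels_true[few])),
    "at least 4 samples")
})

test_that("cluster filtering is a no-op without planted discordance", {
  cfg <- sim_config(n_genes = 200,
                    n_samples = c(SCLC = 10, LCNEC = 10, CARCI = 10,
                                  ADC = 10, SCC = 10),
                    n_planted_pairs = 10, effect_size = 4)
  tr <- simulate_expression(cfg, seed = 51)
  suppressWarnings(p_off <- train_panel(tr$matrix, tr$labels_true))
  suppressWarnings(p_on <- train_panel(
    tr$matrix, tr$labels_true, cluster_filter = TRUE,
    cluster_config = consensus_config(k_range = 2, n_resamples = 50,
                                      n_top_genes = 100, seed = 1)))
  expect_equal(lapply(p_on$steps, `[[`, "pairs"),
               lapply(p_off$steps, `[[`, "pairs"))
  expect_true(all(lengths(p_on$training$removed_samples) == 0))
})
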