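---
title: "Rank-based gene-pair panels for lung neuroendocrine subtyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopanel)
```

## The classification problem

Lung tumors divide into neuroendocrine (NE) subtypes — small-cell carcinoma
(SCLC), large-cell neuroendocrine carcinoma (LCNEC) and carcinoid (CARCI) —
and non-NE subtypes (adenocarcinoma and squamous cell carcinoma). The
subtypes need different treatment, yet they are hard to separate
morphologically, especially on small biopsies and degraded FFPE material.
Quantitative expression signatures struggle in exactly those settings because
absolute expression levels shift with platform, batch and RNA quality.

`reopanel` instead classifies with *within-sample relative expression
orderings* (REOs): for a gene pair $(G_a, G_b)$ only the qualitative pattern
$E_a > E_b$ versus $E_a \le E_b$ inside one sample is used. Any strictly
increasing transformation of a sample's values — quantile normalization,
log transforms, scaling, many batch distortions — leaves every REO unchanged,
so a REO classifier needs no cross-sample normalization and can be applied to
a single profile in isolation.

## The hierarchical panel and its voting rule

A *signature* is a set of gene pairs, each gene appearing in at most one
pair, with the convention that $E_a > E_b$ is a vote for the signature's
positive class. A sample is called positive when **strictly more than half**
of its evaluable pairs vote positive. Three binary signatures are arranged in
a decision tree:

1. **NE-signature** (22 pairs in the built-in panel): non-NE stops here;
2. **CARCI-signature** (30 pairs): positive terminates as carcinoid;
3. **SCLC-signature** (40 pairs): positive is SCLC, negative LCNEC.

Pairs whose genes are undetected in a sample are removed before voting and
the majority rule is applied to the remainder — this is the degradation
fallback that keeps the panel usable on FFPE and biopsy profiles. The
one-pair-per-gene constraint bounds the damage any single gene's dropout can
do to one vote.

Edge cases are resolved explicitly rather than silently:

* a tie $E_a = E_b$ falls into the $\le$ branch and therefore votes
  *against* the positive class (the dichotomy is exhaustive);
* an exact 50/50 vote split fails the strict-majority test, calls the
  negative class, and flags the result `borderline`;
* a signature with *no* evaluable pairs abstains; an abstention at any tree
  step yields the final label `UNDETERMINED`, which evaluation counts as an
  error. Defaulting to a class instead would fabricate a diagnosis;
* fewer evaluable pairs than half the signature (configurable via
  `min_evaluable_frac`) raises a `low_coverage` flag without changing the
  call.

## Signature discovery

`build_signature()` reconstructs a binary signature from a labelled training
matrix in five deterministic stages; `train_panel()` composes three of them
into the tree above (all samples for NE vs non-NE, the NE samples for CARCI
vs non-CARCI, then SCLC vs LCNEC).

1. **Candidate genes.** A pooled-variance two-sample *t* test per gene with
   Benjamini–Hochberg adjustment; genes at FDR < 5% are differentially
   expressed, and the 1,000 with the largest absolute log2 fold changes
   become candidates. A configuration flag declares whether the input is on
   a log-like scale (fold change as mean difference) or linear (ratio of
   means); this is never guessed from the data.
2. **Reversed pairs.** For every unordered candidate pair, a 2×2 table of
   GT/LE counts in the two groups is tested with a two-sided Fisher exact
   test; BH-FDR < 5% across all tested pairs defines significantly reversed
   pairs, oriented so GT is the positive-group pattern. Orientation happens
   after testing: the test itself is directionless.
3. **Apparent accuracy.** Each pair is scored by its concordance with the
   training labels, $S/N \times 100$, predicting positive exactly when the
   pattern is GT. "Apparent" marks the fact that pathological labels are
   themselves imperfect.
4. **Rank-difference score.** Within each sample, genes are ranked over the
   candidate set (fractional ranks for ties) and the absolute rank
   difference of the pair is taken; the score is the product of the two
   groups' geometric means of those differences. A large score means the
   ordering rests on a wide expression gap and is robust to noise.
5. **De-redundant selection.** Pairs are sorted by apparent accuracy, then
   rank-difference score, then lexicographic gene IDs, and accepted greedily
   while both genes are unused. The declared total order makes the result
   deterministic and independent of input order.

Numerical choices worth recording: exact-zero rank differences are floored at
0.5 before the geometric mean (the logarithm is otherwise undefined; 0.5 is
the smallest possible nonzero fractional-rank gap, so the floor never
reorders informative pairs). The rank-difference score multiplies the two
group means without an outer square root; taking the root would be monotone
in the product, so selection is unaffected, and the product form is what the
selection rule uses. Ranks are computed over the candidate set rather than
the whole transcriptome so that the score is reproducible from the
candidates alone; scores therefore change with the candidate universe, but
only as a common monotone rescaling within one discovery run.

## Consensus-clustering sample filtering

Histopathological training labels contain mistakes. Before each discovery
step, `train_panel(cluster_filter = TRUE)` can drop samples whose expression
pattern contradicts their label: samples are repeatedly subsampled (80% by
default), clustered with Ward linkage on Pearson-correlation distance over
the 1,000 most variable genes, and the fraction of co-clustered draws forms
a consensus matrix per candidate $k$. Each of the two clusters at $k = 2$ is
named by the majority pathological side of its members (an exact 50/50 split
is an error, never a silent choice), and samples sitting in the wrong-named
cluster are removed.

For choosing $k$, the classical visual rule — the first flattening of the
consensus CDF — needs an operational form. The relative gain in area under
the CDF with a fixed threshold turned out to misbehave on cleanly separable
data: splitting a pure cluster still inflates the CDF area, because the
randomly split within-cluster pairs acquire intermediate consensus. We
therefore choose $k$ by the PAC criterion: minimize the proportion of sample
pairs with ambiguous consensus (default band 0.1–0.9), ties to the smaller
$k$. On separable two-group data this selects $k = 2$ with PAC $= 0$; the
per-$k$ CDF areas and their relative gains are still reported for
inspection.

## The synthetic-data generator

`simulate_expression()` provides ground-truth datasets so that every stage —
voting, discovery, filtering — is testable without external downloads. Its
defaults are fixed study conditions, not tuning knobs: five subtypes with
sample counts matching a surgical lung-cancer training cohort (21 SCLC,
56 LCNEC, 24 CARCI, 85 ADC, 61 SCC), log2-intensity-like values (baseline 8,
noise SD 1) and 30 planted pairs per hierarchy step at effect size 3 (in
noise-SD units). For each planted pair the two genes' means are offset by
$\pm$(effect size × SD) in the step's positive group and the offset is
reversed in the negative group, producing exactly the reversed-REO structure
the discovery pipeline searches for; samples outside a step's two groups
stay at baseline. Dropout is missing-at-random at a configurable rate
(biopsy/FFPE emulation), and label corruption reassigns a configurable
fraction of samples (chosen uniformly; count = rate × n rounded) to a random
other subtype while recording the truth.

Planted pairs occupy gene slots determined by the configuration alone, not
the seed, so two datasets simulated from the same configuration at different
seeds share their planted truth — that is what makes honest held-out
evaluation of a trained panel possible.

The generator emulates what the method is sensitive to (reversed orderings,
noise, dropout, mislabelling) and deliberately not what it is invariant to:
there is no platform, batch or 3'-bias structure, because REO invariance
under monotone within-sample distortion is established directly by property
tests over random increasing transforms. Gaussian noise is an analytic
convenience (it gives closed-form tail probabilities for planted-pair
frequencies), not a claim about microarray error distributions.
Consequently, passing tests demonstrate correctness of the algorithms under
the stated generative model — they do not certify accuracy figures on real
cohorts.

## Problem sizes in the shipped checks

The test-suite and acceptance computations use deliberately desk-scale
problems: 200-gene/40-sample null matrices (10 replicates) for type-I
control of pair mining; 300 genes, 30 + 30 samples and 15 planted pairs for
discovery recovery; 400 genes and 15 samples per subtype for end-to-end
panel training with held-out evaluation; 60-sample two-group sets with 15
planted label swaps and 100 consensus resamples at $k = 2$ for filtering
recovery (the 1,000-resample, $k$ = 2–10 defaults remain in place for real
use). Exhaustive oracles cover what can be enumerated: all vote
configurations for signatures of up to six pairs, and all 2×2 tables with
group sizes up to 30 against an independent hypergeometric-sum
implementation of the two-sided Fisher p value.

## Known limitations

* The built-in panel is shipped as a fixed, validated resource; the package
  does not attempt to re-derive it from public cohorts, which would depend
  on accession downloads and annotation-release details.
* Vote fractions are not calibrated probabilities; no confidence measure
  beyond the vote tally and coverage flags is defined.
* Discordance filtering is defined only for binary steps ($k = 2$); the
  package does not interpret higher-$k$ structure.
* Typical versus atypical carcinoid is outside the panel's vocabulary.
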