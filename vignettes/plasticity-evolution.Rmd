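---
title: "Models and methods: expression plasticity and its evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: expression plasticity and its evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevo)
```

## The design and the decomposition

The package analyses a reciprocal-transplant design: birds from two
ancestral lowland populations (L1, L2) and one derived highland population
(H) are acclimated to a low-altitude garden (l) and a high-altitude garden
(h), and bulk expression is profiled per bird. Four normalized group means
per gene support a decomposition of expression change, all in log2 units:

* `PC  = L_h - L_l` — the ancestral *plastic* response to the novel
  environment;
* `GC  = H_h - L_h` — the *genetic* divergence, measured where the derived
  population is adapted;
* `GC_b = H_l - L_l` — the same population contrast "back" in the
  ancestral environment;
* `TC  = H_h - L_l = PC + GC` — the total change across native sites.

Because every quantity is a difference of log2 group means under one shared
normalization, the identity `TC = PC + GC` is exact in this package, not
approximate. This is the reason the contrast estimator uses plain
normalized group means rather than shrunken GLM coefficients: fold-change
shrinkage would break the additivity that the downstream geometry
(reversing-vs-reinforcing, ratio classification) relies on.

Plasticity is *reinforcing* when PC and GC share a nonzero sign and
*reversing* when they oppose. A purely geometric consequence, which the
test suite checks by simulation: if PC and TC are independent zero-mean
variables and `GC = TC - PC`, every gene with `|PC| > |TC|` necessarily
reverses and exactly half of the genes with `|PC| < |TC|` do, so the
overall reversing fraction is bounded below by one half. Reversing
prevalence by itself is therefore weak evidence; the interesting signal is
its excess over this bound.

## Contrast estimation

`estimate_contrast()` implements a negative-binomial group contrast:

1. Median-of-ratios size factors (`size_factors()`): the reference is the
   per-gene geometric mean over samples with nonzero counts; a sample's
   factor is the median ratio over genes it expresses, rescaled to
   geometric mean one.
2. Per-gene dispersion by pooled method of moments across the two groups
   under `Var = mu + alpha mu^2`, floored at 1e-8, then shrunk halfway to
   a least-squares trend `alpha(mu) = a/mu + b`. The trend stabilizes
   small-sample moment estimates without the full machinery of an
   empirical-Bayes fit.
3. `log2fc = log2((mA + eps)/(mB + eps))` with `eps` equal to half a count
   on the normalized scale (0.5 divided by the harmonic-mean size factor).
   The pseudo-mean keeps on/off genes finite at the cost of a shrinkage
   bias that is negligible above a few dozen counts; tests that quantify
   estimator accuracy therefore condition on adequately expressed genes.
4. A delta-method standard error,
   `Var(mean) = n^-2 * sum_s (mu/f_s + alpha mu^2)`, and a Wald p-value,
   BH-adjusted over estimable genes (nonzero in at least one group).

The null calibration of this estimator is tested directly: on 5,000
simulated null genes at n = 20 vs 20 the p-value distribution is uniform
within a Kolmogorov distance of 0.05.

## Adaptation-associated (ACDE) gene selection

`pi_value()` combines magnitude and significance,
`pi = |log2fc| * (-log10 p)`, using raw p-values: the selection is purely
rank-based within a fixed contrast, and a uniform monotone re-scaling of
the p-values would not change the selected set, so the unadjusted value is
the least ambiguous choice. `acde_select()` ranks
`dpi1 = pi(HL1) - pi(L1L2)` and `dpi2 = pi(HL2) - pi(L1L2)`, keeps genes
at or above the (1 - q) empirical quantile of both (ties at the boundary
included, q = 0.05 by default), and flags as ACDE the selected genes whose
two highland contrasts agree in sign.

The concordance null is 0.67 because, under iid per-population drift of
expression, the two contrasts H - L1 and H - L2 share the H term and
correlate 1/2; the probability that two standard bivariate normals with
correlation 1/2 share a sign is 2/3. `neutral_concordance()` verifies this
by direct simulation and the acceptance suite requires agreement within
plus or minus 0.01 at 100,000 genes.

## The parametric bootstrap and its real error rate

PC and GC share the lowland samples, so pure sampling noise pushes their
estimates in opposite directions and inflates naive reversing calls (to
two thirds under a complete null, as the shared-term simulation in the
test suite shows). `bootstrap_classify()` applies the countermeasure:
draw (PC*, GC*) from independent Gaussians centred on the estimates with
SDs equal to the standard errors, B = 1000 times, and accept a direction
class only if it recurs in at least 950 draws. The draws are independent
Gaussians even though the estimates are correlated — that is the procedure
as practised, and the correlation is the very artifact the support
threshold is meant to absorb, not a parameter of the bootstrap.

Two calibration facts, both verified in the tests, deserve explicitness:

* If a gene's *estimate* is exactly null (PC-hat = 0), each replicate is a
  fair coin for the PC sign and the support probability is
  `P(Binom(1000, 1/2) >= 950) < 1e-180` — the rule essentially never fires.
* If the estimates themselves carry the sampling noise (the realistic
  case: PC-hat = a - b, GC-hat = c - a with a, b, c iid and SE equal to
  the true sampling SD), the rule fires when both |z| scores exceed
  roughly 1.8 in opposite directions. For the bivariate normal with
  correlation -1/2 this happens for about 1.6% of null genes — a fifty-fold
  reduction of the naive artifact, not its elimination. The package's
  tests assert this rate against its analytic value rather than pretending
  the rule is error-free; consumers should treat "supported" calls on
  weak-effect genes accordingly.

For 5-sigma-separated true effects the correct class is supported in more
than 99% of genes.

## Persistence versus evolution of plasticity

`classify_evolution()` uses the ratio `r = GC_b / GC` with half-open
intervals closed on the left (a declared convention; exact boundary
handling is not derivable from the verbal definitions): *persisting* for
r in [0.5, 1.5), *evolved* for r in [-0.5, 0.5), otherwise unclassified.
The finer schemes order three bins ([0.75, 1.25), [0.25, 0.75),
[-0.25, 0.25)) and four bins ([0.83, 1.17), [0.50, 0.83), [0.17, 0.50),
[-0.17, 0.17)) from low to high degree of plasticity evolution. Genes with
GC exactly zero are excluded rather than given a conventional ratio.
`interaction_magnitude()` supplements the bins with a continuous measure,
the reaction-norm divergence `|(L_h - L_l) - (H_h - H_l)| = |GC_b - GC|`,
estimated from the same group-mean machinery.

## The co-expression stage

The network is built on the pooled lowland samples from both gardens (the
ancestral population's co-expression in the face of environmental change):

* `mad_filter()` removes genes with zero median absolute deviation, whose
  profiles produce spurious correlations.
* `bicor_matrix()` implements the biweight midcorrelation: profiles are
  median-centred, scaled by 9 MAD, Tukey-biweighted, and correlated; a
  side-specific cap rescales the standardized deviations so that at most
  `max_p_outliers = 0.1` of samples per tail can receive zero weight.
  Zero-MAD genes (possible when the filter is bypassed) fall back to
  Pearson standardization per gene, with a warning.
* `signed_adjacency()` maps correlations through `((1 + cor)/2)^beta`, so
  anticorrelated genes get near-zero adjacency and modules form around
  positive co-regulation only.
* `pick_beta()` scans powers 2, 4, ..., 30 and takes the smallest with a
  signed scale-free fit R^2 above 0.8 whose mean connectivity stays above
  a floor (default 30; connectivity shrinks monotonically in beta, and an
  overly sparse network carries no ranking information). The scale-free
  fit bins connectivity into ten equal-occupancy bins and regresses the
  log frequency *density* (frequency over bin width) on log mean
  connectivity — with equal-occupancy bins the raw frequencies are
  constant by construction, so density is the quantity that is log-log
  linear under a power law. The R^2 is reported negative when the slope is
  positive.
* `tom_similarity()` computes the topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` (sum
  over u distinct from i, j), checked in the tests against a brute-force
  double-loop oracle.
* `detect_modules()` clusters 1 - TOM by average linkage and applies an
  adaptive branch cut: the tree is cut at the merge-height quantile mapped
  from the deep-split level (0..3 onto 0.95, 0.97, 0.99, 0.995; default 2)
  and branches below the minimum size (default 30) stay unassigned. This
  is the "tree"-style variant of dynamic cutting — fully specified by two
  parameters — rather than the hybrid PAM-like variant; module counts are
  therefore not expected to match any particular published analysis, and
  the tests assert recovery of planted partitions, not counts.
* `intramodular_connectivity()` sums each gene's adjacencies within its
  module ("within-module" resolving the ambiguity of "sum of its
  adjacencies" toward the standard intramodular definition) and scales by
  the module maximum for cross-module comparability.

## The synthetic-data generator

`sim_config()` fixes the study conditions the package is validated under;
`generate_truth()` and `simulate_counts()` realize them:

* Design: 10 highland birds per garden and 5 per lowland population per
  garden (40 birds), acclimated 35-94 days — the reciprocal-transplant
  census the analysis is shaped around. Tests scale cells up when a
  property needs replication (e.g. 20 per cell for parameter recovery).
* Counts: `NB(mean = f_s 2^(mu_g + X_gs), dispersion alpha_g)` with
  log-normal library factors (sd 0.25, geometric mean 1), baseline log2
  means `N(7.3, 2)` — about 400 counts per gene on average, matching a
  bulk experiment of ~8 million read pairs over ~20,000 genes — and
  dispersions log-uniform on [0.01, 0.5], the typical bulk RNA-seq range.
* Effects: 10% of genes carry effects; |PC| and |GC| are Gamma(2, 0.75)
  (mean 1.5 log2 units); 60% of effect genes reverse; 70% evolve
  (GC_b drawn uniformly within a quarter of GC around zero), the rest
  persist (GC_b = GC exactly). These effect-size settings are free
  parameters of the generator — the real data's effect distribution is
  not published — chosen once as plausible bulk-transcriptome values.
* Structure: five modules of 50 genes with shared latent Gaussian factors
  (per-gene loadings uniform on 0.5-1 times the strength setting), a 2%
  fraction of duration-sensitive genes with a one-log2-unit-per-bin drift,
  and 1% constant (MAD-zero) genes.

What the generator does *not* emulate: GC-content or length biases,
batch-specific chemistry, correlated dispersion-mean outliers, developmental
(irreversible) plasticity, or any read-level artifacts. Passing tests
demonstrate statistical correctness of the machinery under the stated
model, not robustness to everything real data can do.

## Numerical choices and degenerate inputs

* p-values from Wald and chi-square tails are clamped at the smallest
  positive double before BH adjustment.
* Genes with zero counts in both contrast groups are flagged
  non-estimable and excluded from testing; genes with GC = 0 are excluded
  from ratio classification; exact PC or GC zeros give an "undefined"
  direction and are excluded from frequency tests.
* The duration screen skips a stratum (with a warning) when only one
  duration bin is occupied, and tunes its independent-filter threshold per
  stratum over the grid {0, 1, 2, 5, 10, 20} by maximizing discoveries.
* Fisher tests on tables with a zero margin return p = 1 with a warning;
  2xC tables too large for exact enumeration use a seeded Monte-Carlo
  p-value with 1e5 draws.
* Ties: quantile thresholds in ACDE selection keep boundary ties; rank
  statistics use average ranks with the standard tie corrections.
* All stochastic stages take explicit seeds; the pipeline derives fixed
  per-stage substreams from one global seed so that disabling a stage
  never changes another stage's randomness.

## Problem sizes used in validation

The test suite runs the full battery at deliberately desk-sized scales:
5,000 genes and 20 birds per cell for parameter recovery, 10,000 genes for
bootstrap calibration, 100,000 draws for the analytic nulls, 100-600 genes
for network and pipeline integration. These sizes give the Monte-Carlo
error margins quoted in the tests; nothing in the method is
size-limited beyond memory for the gene-by-gene correlation matrix
(the network stage is quadratic in retained genes).

## Known limitations

* The bootstrap treats PC and GC draws as independent; the ~1.6% residual
  false-support rate under shared-term noise (see above) is the price of
  following the practised procedure rather than modelling the estimate
  covariance.
* The group-mean contrast trades the efficiency of a full GLM fit for
  exact additivity; with very low counts its pseudo-mean bias compresses
  estimates toward zero.
* The adaptive tree cut is a two-parameter simplification of dynamic
  branch cutting; fine module substructure that the hybrid variant would
  resolve may stay merged.
* Enrichment assumes the annotation's term-to-gene map is already
  propagated; no ontology-graph propagation is performed.
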