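# plastevo

Tools for analysing **gene expression plasticity and its evolution** in
reciprocal-transplant designs: an ancestral (lowland) lineage and a derived
(highland) population are each acclimated to common gardens at both native
altitudes, and per-gene expression changes are decomposed into

- **PC** — the plastic change: the ancestral populations' response to the
  novel (high-altitude) garden, in log2 units;
- **GC** — the genetic change: the highland-vs-lowland contrast measured in
  the high-altitude garden;
- **GC_b** — the same population contrast measured "back" in the ancestral
  low-altitude garden;
- **TC = PC + GC** — the total change between populations in their native
  environments.

From these the package classifies each gene's ancestral plasticity as
*reinforcing* (PC and GC share a sign) or *reversing* (opposite signs),
screens those calls with a parametric bootstrap (1000 Gaussian draws per
gene from the estimate and its standard error; a class must recur in >= 950
draws), and classifies the plasticity as *persisting* (GC_b/GC in
[0.5, 1.5)) or *evolved* (GC_b/GC in [-0.5, 0.5)), with finer 3- and 4-bin
schemes and a continuous reaction-norm-divergence measure
|(L_h - L_l) - (H_h - H_l)|.

Around this core the package provides:

- adaptation-associated gene selection by the **pi statistic**
  (pi = |log2FC| x -log10 p) and its contrasts
  Delta-pi1 = pi(H vs L1) - pi(L1 vs L2), Delta-pi2 = pi(H vs L2) - pi(L1 vs L2),
  with a top-5% intersection, a sign-concordance gate, and an exact binomial
  test against the neutral concordance null of 0.67 (= 2/3, the same-sign
  probability of two contrasts sharing a reference under iid drift);
- a negative-binomial group-contrast estimator (median-of-ratios
  normalization, moment dispersion shrunk to an a/mu + b trend, Wald tests)
  whose group-mean form makes TC = PC + GC hold exactly;
- a confounder screen for unequal acclimation durations (binned > 30 / > 60 /
  > 90 days; NB likelihood-ratio tests per stratum with independent
  filtering);
- a signed weighted co-expression network built from first principles:
  biweight midcorrelation with side-specific outlier capping, signed
  adjacency ((1 + cor)/2)^beta, scale-free-fit soft-threshold selection,
  topological overlap, adaptive tree cutting, and intramodular connectivity
  k_IM (raw and per-module scaled);
- the inference battery (exact binomial, 2xC Fisher with post hoc tests,
  Kruskal-Wallis + Dunn, one-sided Spearman, level-wise BH term enrichment);
- a synthetic count-data generator with known per-gene ground truth
  (PC/GC/GC_b effects, module loadings, duration confounders, NB noise)
  so every stage is testable without any data download.

## Worked example

```r
library(plastevo)

cfg   <- sim_config(n_genes = 1000, seed = 1)   # Table-1-like design, 40 birds
truth <- generate_truth(cfg)
cm    <- simulate_counts(truth, make_design(cfg), seed = 2)

pc  <- pipeline_config(beta = 6, min_module_size = 30, seed = 1)
res <- run_pipeline(pc, cm)

attr(res$acde, "summary")
#> n_selected n_concordant
#>         38           38
res$concordance$pvalue
#> 3.02e-07
table(res$plasticity$supported_class[res$plasticity$supported_class != "none"])
#> reinforcing   reversing
#>          24          40
res$associations$kim_by_evolution$pvalue
#> 0.00692
```

Reading the output: of 1000 simulated genes, 38 passed both top-5% Delta-pi
gates and all 38 were sign-concordant across the two highland contrasts —
far above the 0.67 neutral expectation (exact binomial p = 3e-07). Sixty-four
genes carried a bootstrap-supported direction call, and genes whose
plasticity evolved had significantly lower intramodular connectivity than
genes whose plasticity persisted (Kruskal-Wallis p = 0.007), the package's
headline association between network position and plasticity evolution.

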