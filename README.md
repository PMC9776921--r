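# mdcnet

Differential gene co-expression analysis for two-condition expression
cohorts, built around the **modular differential connectivity (MDC)**
statistic. The motivating application is transcriptomics of
atherosclerotic plaque progression — contrasting non-plaque with plaque
tissue, and early with advanced lesions, across two independent cohorts —
but every function works on any pair of two-group, gene-by-sample
log-scale expression matrices.

## What it computes

Beyond asking which genes change in *mean* expression, the analysis asks
which gene **modules** change in *co-regulation*. For a co-expression
module with member genes \(g_1,\dots,g_k\),

    MDC = r̄_A / r̄_B,

where r̄_c is the mean absolute pairwise Pearson correlation of the
module's genes over condition *c*'s samples. MDC > 1 means the module is
more tightly co-regulated in condition A; significance comes from a
label-shuffling permutation test, two-sided on |log2 MDC| with a
pseudocount: p = (1 + #{|log2 MDC_perm| ≥ |log2 MDC_obs|}) / (1 + n_perm).

Around this core the package provides the complete analysis graph:

* `two_group_test()`, `select_top_k()`, `common_pattern_genes()` — Welch
  differential expression with BH adjustment, top-500 pattern selection
  and cross-cohort intersection;
* `adjacency_matrix()`, `topological_overlap()`, `detect_modules()`,
  `module_eigengenes()`, `kme()` (or `fit_coexpression_network()` in one
  call) — unsigned WGCNA-style network construction;
* `mdc_statistic()`, `mdc_permutation_test()` — the MDC core;
* `gsea_enrichment_score()`, `gsea_permutation_p()`,
  `ora_hypergeometric()`, `pathway_membership_counts()` — running-sum and
  over-representation enrichment;
* `ppi_degree_rank()`, `module_overrepresentation()`,
  `select_key_genes()` — key genes as the intersection of top-20 PPI
  degree, top-20 pathway-membership count and |kME| > 0.85 within an
  enriched module;
* `cross_validated_roc()`, `random_gene_baseline()` — a ridge-logistic
  signature classifier with stratified 3-fold cross-validation;
* `sim_config()`, `simulate_paired_cohorts()`, `simulate_ppi()`,
  `simulate_gene_sets()` — a synthetic two-cohort generator with planted
  modules, condition-specific correlations, shared DE genes, key genes,
  aligned gene sets and a hub-concentrated PPI graph, returning the
  ground truth every test validates against;
* `run_pipeline()` — the nine-stage end-to-end run with TSV intermediates
  and a JSON manifest, deterministic under one seed.

A thin command-line front end with subcommands (`simulate`, `diffexpr`,
`enrich`, `network`, `mdc`, `keygenes`, `classify`, `run`) ships in
`inst/cli/mdcnet.R`.

## Worked example

Run the full pipeline on the default synthetic two-cohort study (32+32
and 13+16 samples, 1000 genes, five planted modules, 8 planted key
genes):

```r
library(mdcnet)
cfg <- pipeline_config(simulation = sim_config(), seed = 1)
man <- run_pipeline(cfg, "example_run")
print(man)
```

```
run_manifest: 9 stages in 13.7 s -> example_run
  data                 0.15 s  6 file(s)
  diffexpr             0.02 s  2 file(s)
  common_genes         0.00 s  1 file(s)
  enrichment           6.65 s  3 file(s)
  coexpression         0.57 s  6 file(s)
  mdc                  6.08 s  2 file(s)
  module_enrichment    0.00 s  2 file(s)
  keygenes             0.13 s  1 file(s)
  classify             0.11 s  1 file(s)
  key genes: G0001, G0002, G0003, G0004, G0005, G0006, G0007, G0008
```

The cohort-1 MDC table shows which detected modules change connectivity
between the conditions — module 2 (planted per-condition correlations
0.7 vs 0.3) roughly doubles its connectivity, module 3 (0.3 vs 0.7)
halves it, and the permutation p hits the 1/1001 floor for both:

```r
print(man$results$mdc[[1]])
```

```
mdc_result: 5 modules, 3 significant (permutation p < 0.05)
 module n_genes r_bar_a r_bar_b   mdc log2_mdc  p_value significant
      1     147   0.220   0.186 1.186   0.2463 0.000999        TRUE
      2      82   0.728   0.362 2.009   1.0061 0.000999        TRUE
      3      54   0.272   0.725 0.375  -1.4137 0.000999        TRUE
      4      50   0.557   0.386 1.441   0.5270 0.070929       FALSE
      5      44   0.595   0.615 0.968  -0.0476 0.795205       FALSE
```

The key-gene stage intersects the three criteria and returns exactly the
8 planted key genes, each with high candidate-subgraph degree, membership
in all 15 planted signature pathways, and |kME| well above 0.85 in the
enriched module:

```r
print(man$results$key_genes)
```

```
key_gene_report: 76 candidate(s), 8 key gene(s)
  key genes: G0001, G0002, G0003, G0004, G0005, G0006, G0007, G0008
 gene_id degree pathway_count best_abs_kme
   G0001     25            15        0.938
   G0002     23            15        0.960
   ...
   G0008     25            15        0.941
```

Finally the signature classifier on the small cohort (13 vs 16 samples)
separates the conditions far better than random 8-gene signatures:

```r
print(man$results$classifier$roc)
mean(man$results$classifier$baseline)
```

```
roc_result: 3-fold CV on 8 genes; fold AUC 0.933, 0.900, 1.000; average 0.944
random 8-gene baseline: mean AUC 0.691
```

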