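# reosig

Rank-based gene-pair signatures that survive RNA degradation.

Formalin-fixed paraffin-embedded (FFPE) tissue is by far the most abundant
clinical specimen, but fixation and storage partially degrade RNA, shifting
the measured expression of thousands of genes by two-fold or more relative
to matched fresh-frozen (FF) tissue. Any classifier built on absolute
expression levels (risk scores, thresholds) therefore does not transfer
between the two materials. The *relative expression ordering* (REO) of a
gene pair within one sample — simply whether gene *i* is measured above or
below gene *j* — is far more robust: most orderings survive degradation, and
the ones that do not are concentrated among pairs with near-equal
expression.

`reosig` implements the full REO toolchain for transcriptomics researchers
who want degradation- and batch-robust classifiers:

- **Consistency scoring** — for each FF/FFPE sample pair, the score
  *k/n* over all C(G, 2) gene pairs (*n* evaluable pairs, *k* with the same
  ordering in both samples), optionally after excluding the
  `floor(f * n_pairs)` pairs with the smallest within-sample rank difference
  `R_ij = |R_i − R_j|` in the FF sample (`f` = 0, 0.1, 0.2 by default).
- **Stable-REO mining** — gene pairs ordered the same way in ≥ 99% of an
  accumulated normal cohort, and the fraction of those orderings maintained
  in individual FFPE samples.
- **Reversal-pair signatures** — pairs whose ordering holds in > 85% of one
  phenotype and is reversed in > 85% of the other, ranked by
  `avgRij = mean[Rij(class0)] * mean[Rij(class1)]` (the product is
  ranking-equivalent to the geometric mean of the two class means), with the
  odd top *k* kept as the signature.
- **Majority-vote classification** — a sample is labelled class 0 iff more
  than half of the signature pairs show the class-0 ordering; ties never
  count toward class 0. Invariant under any strictly increasing
  transformation of a sample's values, hence free of normalization.
- **Paired Rank Product** — degradation DEGs from the geometric mean of
  within-pair fold-change ranks, with permutation p-values and the
  `E[FP]/rank` false discovery estimate, plus fold-change binning and a
  cross-tissue direction-consistency binomial test.
- **Synthetic paired cohorts** — a seeded generator of FF/FFPE pairs with
  gene-specific, tissue-independent log-space degradation and two-phenotype
  cohorts with implanted reversal pairs, so the whole pipeline is testable
  without external downloads.

All user-facing functions take a data frame (genes in the first column,
samples in the remaining columns) or a plain matrix, return tibbles, and
chain with the pipe. The heavy all-pairs kernels are C++ and stream over
pair blocks, so 20,000-gene profiles (2 × 10⁸ pairs) never materialize a
pair list.

## Worked example

```r
library(reosig)

cfg    <- sim_config(n_genes = 500, n_samples = 40, seed = 1)
ff     <- simulate_ff_cohort(cfg, n_samples = 8)
cohort <- degrade_to_ffpe(ff, cfg)

consistency_summary(cohort_consistency(cohort))
#> # A tibble: 3 × 3
#>   fraction n_samples mean_score
#>      <dbl>     <int>      <dbl>
#> 1      0           8      0.928
#> 2      0.1         8      0.964
#> 3      0.2         8      0.986
```

93% of gene-pair orderings survive degradation, rising to 96% / 99% after
excluding the 10% / 20% of pairs with the closest FF expression — the
unstable orderings live among near-ties.

```r
tc  <- simulate_two_class_cohort(cfg)
sig <- build_signature(tc$class0, tc$class1, threshold = 0.85, k = 5,
                       class0_name = "cirrhosis", class1_name = "hcc")
sig
#> <reo_signature> 5 pairs (cirrhosis vs hcc), threshold > 0.85, 489 candidates
#> # A tibble: 5 × 8
#>   gene_a gene_b class0_direction consistency_class0 consistency_class1
#>   <chr>  <chr>  <chr>                         <dbl>              <dbl>
#> 1 G00005 G00006 gt                                1                  1
#> 2 G00003 G00004 gt                                1                  1
#> 3 G00001 G00002 gt                                1                  1
#> 4 G00009 G00010 gt                                1                  1
#> 5 G00007 G00008 gt                                1                  1
```

The five selected pairs are exactly the five implanted reversal pairs
(`tc$truth`), picked from 489 candidates by the largest `avgRij`. The
signature transfers to degraded material:

```r
test     <- simulate_two_class_cohort(cfg, n_samples = 50, seed = 99)
ffpe_hcc <- degrade_to_ffpe(test$class1, cfg, seed = 100)$ffpe
evaluate_sensitivity(ffpe_hcc, sig, "hcc")
#> # A tibble: 1 × 4
#>   true_label n_samples n_correct sensitivity
#>   <chr>          <int>     <int>       <dbl>
#> 1 hcc               50        50           1
```

`run_reo_pipeline()` chains every stage (consistency, stable-pair mining,
signature training, validation, Rank Product) from one `sim_config()` and
writes deterministic TSV/JSON outputs; `inst/scripts/reo-pipeline.R` wraps
it for the shell. `autoplot()` methods draw the consistency boxplots and
DEG fold-change histograms.

Real datasets enter through `read_expression()` (gene × sample TSV),
`collapse_probes()` (probe-to-gene maps, arithmetic-mean aggregation),
`paired_cohort()` and `accumulate_cohorts()`; the vignette describes how to
point the same pipeline at expression tables exported from GEO, ArrayExpress
or TCGA.

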