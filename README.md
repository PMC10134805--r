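# ecocatalog

Comparative gene-content analysis of metagenome gene catalogs across
ecologies.

## The problem

A nonredundant gene catalog represents each metagenomic sample by the set of
gene clusters (ORFs grouped at a fixed amino-acid identity) assembled in it.
Given such a catalog spanning many *ecologies* — human gut, aquatic sediment,
cow rumen, nasal cavity, ... — this package answers the comparative
questions gene catalogs exist for:

* How similar are two ecologies in gene content, once unequal sample counts
  are controlled for? `subsample_jaccard()` draws `m = 4` samples per
  ecology over 50 iterations and averages the gene-union Jaccard distance
  `d(A, B) = 1 − |A ∩ B| / |A ∪ B|` per ecology pair, with
  `permutation_null()` providing a label-permutation reference.
* How diverse are samples within an ecology? `within_ecology_diversity()`
  pools pairwise Jaccard / Bray-Curtis dissimilarities and Chao1 / Chao2
  richness (`Ŝ = S_obs + f₁²/(2 f₂)`, bias-corrected when `f₂ = 0`) over the
  same subsampling scheme.
* Do samples cluster by gene content alone? `run_lsi_pipeline()` applies
  latent semantic indexing — TF-IDF weighting
  `w(s, g) = [x(s, g)/n_genes(s)] · ln((n+1)/occ(g))`, truncated SVD,
  a 2-D UMAP embedding and HDBSCAN density clustering — over the full
  parameter grid (k ∈ {10, 50, 100}, n_neighbors ∈ {10, 15, 20, 30},
  min_dist ∈ {0.1, 0.25, 0.5}, minPts ∈ {25, 50, 75, 100}), selecting the
  cell with maximal silhouette under a 10% noise cap.
* What characterises each cluster? `functional_enrichment()` (chi-square,
  Fisher below 6 observations per cell) and `taxonomic_enrichment()`
  (one-sided Welch t) with Benjamini–Yekutieli control.
* Which genes are *pan-ecologically conserved* (present in ≥1 sample of
  every ecology, `conserved_genes()`) or confined to an ecology subset and
  differentially abundant there (`ecology_set_genes()`, one-sided
  Mann-Whitney on held-out abundances, BY-adjusted)?

Because real catalogs of this kind are terabyte-scale, the package ships a
synthetic multi-ecology catalog generator (`generate_catalog()`) with
planted, recorded ground truth — conserved genes, group cores,
ecology-specific pools, contrast sets with abundance shifts, a controlled
singleton fraction (default 0.66) — on which the entire pipeline is
exercised and tested end to end.

## Worked example

```r
library(ecocatalog)

cfg  <- catalog_config()                 # 17 ecologies, 3 groups, 8 samples each
cat_ <- generate_catalog(cfg, seed = 1)

singleton_counts(cat_$presence)
#> # A tibble: 1 × 3
#>   n_singleton n_nonsingleton fraction
#>         <int>          <int>    <dbl>
#> 1       17034           8775    0.660

sj <- subsample_jaccard(cat_$presence, cat_$samples, m = 4, iterations = 50, seed = 1)
glance(sj)
#> # A tibble: 1 × 6
#>   n_ecologies     m iterations mean_distance min_distance max_distance
#>         <int> <dbl>      <dbl>         <dbl>        <dbl>        <dbl>
#> 1          17     4         50         0.923        0.740        0.985
autoplot(sj)                             # ordered heatmap of ecology distances
```

About 66% of catalog genes occur in exactly one sample, and ecologies in the
same group (e.g. two gut microbiomes) sit at visibly smaller Jaccard
distance (mean within-group ≈ 0.79 here) than ecologies in different groups
(≈ 0.98); the dendrogram from `order_distance_matrix(sj)` recovers the three
planted ecology groups as contiguous blocks.

Conserved genes and their held-out validation:

```r
cons <- conserved_genes(cat_$presence, cat_$samples)
held <- generate_heldout(cfg, cat_$truth, seed = 1)
prof <- prevalence_profile(cons, held$presence, held$abundance, held$samples)
glance(prof)
#> # A tibble: 1 × 2
#>   n_genes median_prevalence
#>     <int>             <dbl>
#> 1      60             0.956
```

All 60 planted conserved genes are recovered (they occur in every ecology),
and their median prevalence across held-out samples is ≈ 0.95 — the
generator's per-sample dropout rate of 0.05 showing through, since held-out
samples get no rescue step.

The full pipeline, end to end, from one configuration:

```r
run_pipeline(default_run_config(outdir = "run1", seed = 1))
# writes ecology_distances.tsv, clusters.tsv, enrichment_*.tsv,
# conserved_genes.tsv, geneset_*.tsv, manifest.json, ...
```

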