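---
title: "Methods: co-expression networks, module detection and annotation in conetwork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, module detection and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and assumptions

`conetwork` implements a weighted gene co-expression analysis for bulk
transcriptomes of mixed cell populations (the motivating use case is white
blood cells, where modules act as proxies for leukocyte subtype abundance).
The pipeline assumes its input is a **residual expression matrix**: counts
already variance-stabilized and corrected for hidden factors upstream, with
age and sex removed here by per-gene ordinary least squares
(`residualize()`). Residuals are treated as approximately Gaussian; this is
an assumption of the synthetic generator and of nothing else in the
pipeline, since correlations, eigengenes and rank-based rules are all
distribution-agnostic beyond second moments.

# The pipeline

1. **Correlation** — pairwise Pearson correlation between genes; zero
   variance genes are an error (filter first with `filter_genes()`).
2. **Adjacency** — unsigned `|r|^β` (β = 3) or signed `((1+r)/2)^β`
   (β = 10). The signed transform is the standard choice consistent with
   "negative correlations are not considered": a perfect anti-correlation
   maps to adjacency 0. The defaults are deliberately lower than the usual
   12/6 guidance because strong hidden-factor correction upstream already
   flattens the correlation spectrum; `scale_free_fit()` is provided as a
   diagnostic (equal-width binning of connectivity, least-squares fit of
   log10 frequency on log10 mean connectivity, R² returned) but **no
   automatic β selection is performed** — β is a fixed configuration value.
3. **TOM** — `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, diagonal 1,
   diagonal excluded from `k` and `l`. The denominator is provably ≥ 1 for
   adjacencies in [0,1], so no division guard is needed. The same (unsigned)
   TOM formula is used in both modes because the adjacency is already
   non-negative.
4. **Clustering** — average-linkage agglomeration on `1 − TOM`
   (`stats::hclust`). Exactly tied merges can leave float-level height
   inversions; heights are passed through `cummax` (average linkage is
   theoretically monotone) and the cut height receives a `1e-10`-scale
   nudge so ties fall on one side of it.
5. **Hybrid dynamic tree cut** — two deterministic stages:
   - *Stage 1*: cut at `h*`, the q-th percentile (q = 99 − 2.5·deepSplit,
     so 94% at the default deepSplit 2) of merge heights **not exceeding
     0.99 × the maximum height**. Branches with ≥ `min_module_size` (30)
     leaves become modules.
   - *Stage 2 (PAM-like)*: each unassigned gene joins the module with the
     smallest average dissimilarity to its members, provided that average
     is both (a) smaller than the gene's average dissimilarity to all
     genes outside that module and (b) at most `h*`; otherwise it stays
     grey.

   The height ceiling in stage 1 and the radius constraint (b) in stage 2
   are this package's design choices, and they matter. On realistic TOM
   dendrograms the top ~50–60% of merge heights are background–background
   and background–module joins packed into a narrow band just below the
   maximum; a percentile taken over *all* heights therefore cuts above the
   real branch structure and absorbs noise genes into every module.
   Restricting the percentile to heights below 0.99 × max places the cut at
   the top of the genuine branches. Similarly, pure distance *comparison*
   rules in stage 2 absorb background genes, because a noise gene is
   systematically slightly closer (in TOM) to a high-connectivity module
   than to other noise genes; the `h*` radius bound keeps such genes grey
   while still rescuing weak true members that stage 1 missed. Both choices
   mirror the cut-height and maximum-PAM-distance defaults of the reference
   hybrid tree-cut implementation; the planted-module recovery and
   module-size tests pin the behaviour.
6. **Eigengenes** — genes standardized to mean 0 / variance 1, leading
   right singular vector of the module submatrix, rescaled to unit
   variance. Sign: non-negative correlation with the module's mean
   standardized profile; if that profile is exactly degenerate (perfectly
   balanced anti-correlated halves) the first gene's profile is the
   reference, keeping the convention deterministic and permutation-stable.
   A single-gene module's eigengene is the standardized gene itself.
7. **Merging** — repeatedly find the module pair with maximal eigengene
   correlation; merge while it exceeds 0.8, recomputing eigengenes after
   *every* merge (no batching, so the order is unambiguous). The smaller
   module is absorbed into the larger; size ties resolve toward the
   colour-vocabulary order. The literal "Pearson correlation > 0.8" rule
   is used rather than a dendrogram-height variant.
8. **Membership and hubs** — MM is the gene × eigengene Pearson
   correlation. Within each module, `q(|MM|) = rank/size` with ties
   averaged (the gene itself included). Hubs: `1 − q < 0.10` (top 90th
   quantile). Not clearly assigned: `|MM| < 0.10`. Function prediction
   (guilt by association): `|MM| > 0.20` in a module that carries a
   user-supplied function label — the package never hard-codes biological
   labels.

# Annotation statistics

- **Marker-list enrichment**: upper-tail hypergeometric
  `P(X ≥ overlap)`, Bonferroni over all module × list tests. Lists are
  intersected with the analysis universe first.
- **Trait correlation**: Pearson on pairwise-complete samples (traits such
  as FACS counts are typically available for a sample subset), Student
  asymptotic p with n − 2 degrees of freedom, `n_used` always reported.
  Multiple testing: Bonferroni across all module × trait pairs — the
  correction method is a package choice (the enrichment stage's convention
  is reused); raw p-values are kept in the output.
- **Cross-tabulation**: two-sided Fisher's exact test per module pair
  (conservative default; the sidedness is recorded here deliberately),
  with a −log10(p) matrix for heatmaps. Query tool 2 instead uses
  one-sided Fisher because its stated purpose is enrichment.
- **Closest partners**: per gene, the co-module gene with maximal
  adjacency; the "important gene" summary filters to `1 − q(|MM|) < 0.20`
  and top adjacency above the empirical 3rd quartile of top adjacencies —
  a data-dependent floor, matching how such cutoffs are quoted in
  practice.

# The synthetic generator

`generate_dataset()` emulates, at reduced scale, a cohort of several
hundred samples with thousands of mixed-biotype transcripts: latent module
factors `f_m` (jointly multivariate normal with a configurable
module–module correlation matrix), gene model
`x = s·w·f_m + sqrt(1−w²)·ε + age_effect·age + sex_effect·sex`, background
genes as pure noise plus covariate effects, traits
`t = loading·f_m + sqrt(1−loading²)·η`, age uniform on 18–102 years, sex
Bernoulli(0.5), an exact-count lncRNA share defaulting to 11% (the rounded
share of lncRNAs in large whole-blood transcript panels), deterministic
gene tiling along chr1..chr22 (10 kb apart, 1 kb long — this makes region
queries exactly predictable), and one marker list per module (the first
half of the module, capped at 10 genes). Defaults (5 modules × 50 genes,
500 background, loadings 0.6–0.9, n = 300, trait loading 0.6) are the
stated validation world and are not tuned.

What the generator does **not** emulate: count noise and library-size
effects (inputs are residuals by construction), heavy-tailed expression,
overlapping modules, gene–gene interactions beyond one factor per gene,
linkage between genomic position and co-expression, and realistic trait
measurement error. A green recovery test therefore establishes correctness
of the machinery under the stated generative model — not performance on
real RNA-seq data.

# Numerical choices and tie-breaking

- All randomness flows from a single integer seed per config; identical
  configs give bitwise-identical datasets and identical pipeline output.
- Ties anywhere (equal dissimilarities, equal ME correlations, equal
  adjacencies in rankings) break toward the lower gene/module index, so
  runs are platform-stable.
- Correlation matrices are symmetrized `(C + Cᵀ)/2` and clamped to
  [−1, 1]; adjacency and TOM are clamped to [0, 1].
- Quantiles use R's default type-7 definition throughout.
- Degenerate inputs have defined behaviour: single-gene modules (eigengene
  = standardized profile), `min_module_size` above the gene count (all
  grey, warning), constant traits (row dropped, warning), rank-deficient
  designs (error naming the collinear column), empty region queries
  (empty table, warning).

# Known limitations

- The hybrid tree cut is a faithful simplification, not a numerical clone,
  of the reference dynamic tree-cut implementation; partitions can differ
  on borderline branches.
- Dense matrices only: memory is O(genes²); the intended scale is up to a
  few thousand genes on a laptop. Block-wise computation is a possible
  extension, not implemented.
- Ordered-query pathway enrichment against external term databases is out
  of scope; marker-list enrichment with user-supplied lists is the
  in-package analogue.
- Eigengene-based merging assumes modules are well-summarised by one
  principal component; strongly heterogeneous modules may merge late or
  not at all.
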