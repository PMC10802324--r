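# pcadsc

Group-aware PCA for molecular profiling matrices, with the **Dispersion
Separability Criterion (DSC)** — a single number, with a permutation-test
p-value, that quantifies how separated pre-defined groups of samples
(batches, shipments, sexes, subtypes) are.

Omics datasets are produced in processing batches, and systematic
non-biological differences between batches can contaminate every
downstream analysis. The standard diagnostic — a PCA plot colored by
batch — shows the problem but does not quantify it. `pcadsc` augments
that plot with group centroids, within-group dispersion rays, ordinal
trend trajectories and dual-variable coloring, and attaches a number to
it.

## The statistic

For k groups with sizes s_j (weights π_j = s_j/N), group means μ_j and
global mean M₀:

    DSC = D_b / D_w
    D_b² = trace(S_b) = (1/N) Σ_j s_j Σ_i (μ_ij − M_i)²
    D_w² = trace(S_w) = (1/N) Σ_j Σ_h Σ_i (x_hij − μ_ij)²

where S_b = Σ_j π_j (μ_j − M₀)(μ_j − M₀)ᵀ and S_w = Σ_j π_j Σ_j are the
between- and within-group scatter matrices. The trace identities reduce
both dispersions to streaming sums (`dsc_fast()`, linear in samples ×
features); the explicit scatter-matrix construction (`dsc_naive()`) is
retained as an independent oracle, and the suite verifies the two agree
to 1e-10. Significance comes from shuffling the group labels with sizes
preserved and reporting the fraction of permuted DSC values ≥ the
observed one. Rule of thumb: DSC < 0.3 low, 0.3–0.6 moderate, > 0.6
strong group separation.

## Worked example

Three synthetic batches of 20 samples, 200 features, with the batch means
one unit apart on every feature:

```r
library(pcadsc)

sp  <- synthetic_spec(n_groups = 3, samples_per_group = 20,
                      n_features = 200, group_mean_shift = 1, seed = 7)
syn <- generate_grouped(sp)

pca <- compute_pca(syn$matrix, 2)
pca
#> pca_result: 60 samples, 2 component(s)
#> explained variance: 41.3%, 2.3%

dsc_report(syn$matrix, pca, syn$annotation, "batch",
           n_perm = 2000, seed = 8)
#> DSC report for 'batch':
#>  variable   space n_samples n_groups    Db     Dw    DSC p_value n_perm
#>     batch overall        60        3 11.80 13.860 0.8511       0   2000
#>     batch   pca-2        60        3 11.67  2.903 4.0185       0   2000
#>  interpretation
#>          strong
#>          strong
```

Reading the output: the batch means sit far apart relative to the spread
within batches — DSC 0.85 on the full 200-feature space ("overall") and
4.0 on the two plotted components, where the shift concentrates. No
permuted labeling out of 2000 reached the observed DSC, so p < 0.0005:
a strong, significant batch effect. The plot to go with it:

```r
cen  <- compute_centroids(pca, syn$annotation, "batch")
spec <- build_plot_spec(pca, cen, syn$annotation, "batch")
spec <- add_trend(spec, cen)             # arrows b1 -> b2 -> b3
render_plot_spec(spec, "batches.png")
```

After per-batch mean-centering (`mean_center_by_batch()`), the same
report drops to DSC ≈ 0 with p = 1 — the before/after workflow used to
judge a batch-effect correction.

A command-line front end wrapping the same functions lives at
`inst/cli/pcadsc.R` (subcommands `run` and `simulate`).

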