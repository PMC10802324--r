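---
title: "Quantifying group separation with the Dispersion Separability Criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying group separation with the Dispersion Separability Criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcadsc)
```

## The problem

Molecular profiling matrices — gene expression, DNA methylation, copy
number, protein abundance — are produced in processing groups: shipments,
plates, centers, time windows. Systematic non-biological differences
between those groups (batch effects) can dwarf the biology of interest, and
the first line of defense is a PCA plot of the samples colored by batch.
Two things are routinely missing from that plot: a visual summary of where
each group sits and how tightly it clusters, and a *number* that says how
separated the groups are, with a significance assessment. `pcadsc`
provides both.

## PCA of samples

Given a feature-by-sample matrix (N features, D samples), each sample is a
point in N-dimensional feature space. We center each feature across samples
and compute the top L directions of maximal variance. The implementation
takes the thin SVD of the centered D×N matrix rather than forming the N×N
covariance matrix: for typical omics data with N ≫ D this is both faster
and numerically better conditioned. The test suite keeps the explicit
covariance eigendecomposition as an independent oracle and checks the two
routes agree to 1e-8 on random instances.

Conventions worth stating because every downstream number depends on them:

* **Variance denominator.** Score variances (the eigenvalues) use
  1/(D−1). Explained-variance fractions are denominator-independent.
* **Sign.** An SVD determines each component only up to sign. We orient
  every component so that its largest-magnitude feature loading is
  positive, ties broken by the lowest feature index, so scores and plots
  are identical across runs and platforms.
* **Default L = 2**, because the diagnostic plots show PC1/PC2; any
  L ≤ min(N, D) is accepted.

Group centroids are arithmetic means of member scores. Since scores are
centered, the size-weighted mean of all centroids is the origin — a cheap
invariant the tests exploit.

## The Dispersion Separability Criterion

For samples assigned to k groups, let s_j be the size of group j,
π_j = s_j/N its weight, μ_j its mean vector and M₀ the global mean. The
between-group and within-group scatter matrices are

* S_b = Σ_j π_j (μ_j − M₀)(μ_j − M₀)ᵀ
* S_w = Σ_j π_j Σ_j, with Σ_j the mean squared-deviation matrix of group j
  about μ_j.

The criterion is the ratio of the square roots of their traces:

> DSC = D_b / D_w, with D_b² = trace(S_b) and D_w² = trace(S_w).

D_b is the size-weighted root-mean-square distance of group centroids from
the global mean; D_w is the root-mean-square distance of samples from
their group centroid. Because a trace of an outer product is a sum of
squares, both reduce to streaming sums over dimensions:

* D_w² = (1/N) Σ_j Σ_h Σ_i (x_hij − μ_ij)²
* D_b² = (1/N) Σ_j s_j Σ_i (μ_ij − M_i)²

`dsc_fast()` computes these sums directly and never materializes a d×d
matrix, so it is linear in samples × dimensions and handles
20,000-feature matrices effortlessly. `dsc_naive()` builds S_b and S_w
explicitly; it exists so the algebraic identity between the two
formulations is *executable* — the acceptance suite checks agreement to
1e-10 relative on 100 random instances (up to 50 samples, 200 dimensions,
6 groups).

A note on the square root: we consistently define D_b and D_w as the
square roots of the scatter-matrix traces, in both implementations, which
is the reading under which the streaming formulas above are exactly
equivalent to the scatter-matrix construction. This also gives DSC the
pleasant properties the tests verify on every instance:

* D_b² + D_w² equals the total mean squared deviation about the global
  mean (law of total variance);
* DSC is invariant under translation, uniform scaling and orthogonal
  rotation of the feature space;
* DSC = 0 exactly when all group means coincide.

**Degenerate inputs.** D_w = 0 with distinct group means (every group
collapsed onto its centroid) leaves the ratio undefined and raises an
error carrying D_b; D_w = D_b = 0 (all samples identical) yields DSC = 0
with a warning. Groups of size one are allowed — they contribute nothing
to D_w — but trigger a warning, because a single outlier far from the
cloud forms exactly this situation and inflates DSC without statistical
support.

### Two reporting spaces

Plots show two components; batch structure may live elsewhere. Reports
therefore quote the DSC twice: **overall** (computed on the full filtered
feature space) and **pca-L** (computed on the L retained score columns,
unweighted — the scores already carry the variance scale). The two can
disagree in either direction, and that disagreement is informative: a high
pca-2 DSC with a modest overall DSC means the separation is concentrated
in the leading components.

### Permutation p-value

Significance comes from a label permutation test: shuffle the group labels
uniformly at random (group sizes fixed), recompute the DSC, and report the
fraction of permuted values ≥ the observed value (ties count toward the
null). The default of 2000 permutations resolves p-values down to 0.0005.
Permutations are sampled with replacement from the assignment space;
duplicates are permitted. The p-value is the plain count/n_perm fraction
by default; an optional (count+1)/(n_perm+1) smoothed estimate is
available for users who prefer a never-zero p-value. A permutation that
lands in the D_w = 0, D_b > 0 corner counts as an infinite DSC — i.e.
toward the null — rather than being dropped, which keeps the test valid.

The calibration test draws 200 independent null datasets (3 groups of 10
samples, 20 dimensions, 200 permutations each) and checks that the
rejection rate at α = 0.05 lands in [0.02, 0.09]; with count/n_perm and
finite n_perm the exact attainable rate is slightly above α, which the
band accommodates.

### Interpreting the value

The rule of thumb encoded in `interpret_dsc()`: DSC < 0.3 — groups are
reasonably consistent ("low", e.g. negligible batch effects); 0.3–0.6 —
"moderate"; above 0.6 — "strong", typically worth correcting before
downstream analysis. The boundary values 0.3 and 0.6 classify as
"moderate": the guidance phrase "between 0.3 and 0.6" does not specify
the endpoints, and the closed interval is the reading that keeps both
thresholds in the middle class. Always read the DSC together with its
p-value: small per-group counts can make a large DSC non-significant
(outliers), and large counts can make a tiny DSC significant.

## Visualization

All geometry is assembled into a declarative `plot_spec` — points,
centroids, rays (centroid → member point segments), trend arrows, axis
labels carrying explained-variance percentages, and legends — which is
what the tests interrogate; rendering to PNG/SVG/PDF is a thin ggplot2
layer on top. Design choices that are cosmetic and therefore simply
documented: centroids are enlarged diamonds, rays are thin and
semi-transparent, trend arrows are black with closed heads, and the DSC
with its p-value goes into the subtitle. The palette is a fixed 20-color
categorical cycle assigned to the sorted level list; beyond 20 levels,
colors recycle and point shapes carry the distinction. Trend order is
numeric when all levels parse as numbers, lexicographic otherwise, or an
explicit list supplied by the user.

## What the synthetic generator emulates

`generate_grouped()` draws spherical Gaussian groups in feature space with
the mean of group j displaced by (j−1)·δ along a chosen subspace
(all features, the first feature only, or a random unit direction);
`generate_trend()` is the same construction driven by a per-step drift
along one fixed direction, with an ordinal batch variable;
`generate_dichotomy()` adds a hidden binary variable ("sex") that shifts a
designated fraction of features by ±effect, with the affected feature IDs
prefixed `sexlinked_` so they can be excluded, and with sex balanced
within each batch so the two variables are unassociated by design.

Default scenario sizes (≤ 60 samples, ≤ 500 features in the tests) keep
every simulation-based check fast while leaving the statistics
well-resolved; the two scales used by specific checks are stated with
those checks (e.g. 500 samples/group for parameter recovery, 200
replicates for null calibration).

For two equal groups with an all-feature shift δ and unit within-group
standard deviation, the population DSC has the closed form
√(Σ π_j ‖μ_j − M₀‖²) / √(Σ π_j d σ²) = δ/2, independent of the number of
features. The parameter-recovery test generates 500 samples per group at
δ/σ ∈ {0.5, 1, 2} and requires the empirical DSC to be within 5% of this
value; averaging three replicates keeps the Monte Carlo error of the
check an order of magnitude below the tolerance.

What the generator does **not** emulate: platform-specific value
distributions (methylation β-values are bounded, counts are discrete and
overdispersed), feature–feature correlation, heavy tails, and missingness
patterns. Passing tests on these Gaussians demonstrate the statistic and
the machinery, not robustness to every real assay; the outlier caveat is
exercised by a dedicated injected-outlier test rather than by a
heavy-tailed noise family.

## Before/after correction workflow

`mean_center_by_batch()` subtracts each feature's batch mean and restores
the global feature mean. It is intentionally the simplest location
correction: it removes a pure mean-shift batch effect *exactly* (the
post-correction between-batch dispersion is identically zero, p = 1),
which makes the before/after DSC workflow crisp to demonstrate and test.
It is a demonstration stand-in in the sense that real pipelines usually
prefer distribution-level corrections (e.g. empirical-Bayes methods that
also shrink scale differences); those are deliberately out of scope here,
and the before/after quantitation works unchanged with any external
correction. The tests also verify the flip side: a correction keyed on
batch leaves the DSC of an independent, within-batch-balanced biological
variable essentially untouched.

## Known limitations

* The DSC has no analytic null distribution here; inference is purely
  permutation-based, and p-values across many annotation variables are
  reported raw, without multiple-testing correction.
* DSC compares *locations*: batch effects expressed purely as variance
  differences leave the group means coincident and are invisible to it.
* The permutation test assumes exchangeability of samples across groups
  under the null; structured designs (paired samples, nesting) violate it.
* 3-D and interactive displays are out of scope; the plot layer is
  deliberately static and two-dimensional.
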