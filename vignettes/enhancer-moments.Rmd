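---
title: "Moment-based enhancer prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based enhancer prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerRF)
```

# The problem

Enhancers are short (roughly 50–1500 bp) DNA segments that boost
transcription of a target gene, often from a large genomic distance and
without a shared sequence motif, which makes them much harder to locate than
promoters. enhancerRF classifies fixed-width sequence windows (nominally
200 bp) in two layers: enhancer vs. non-enhancer, then strong vs. weak
enhancer among the positives. The classifier itself is an ordinary random
forest; the package's substance is the fixed 102-dimensional *super feature
vector* (SFV) that turns a raw A/C/G/T string into numbers that preserve
both composition and sequence order.

# The feature model

## Sequence matrix and statistical moments (30 values)

Each sequence is encoded numerically (default A=1, C=2, G=3, T=4 in
alphabetical order) and reshaped row-major into the smallest square matrix
that holds it: a length-z series gives a d×d matrix with d = ⌈√z⌉, the
remainder zero-padded (200 bp → 15×15). From that matrix we take, up to
combined degree 3 and always in the fixed order
(00, 01, 10, 11, 02, 20, 12, 21, 30, 03):

* **Raw moments** \(A_{jk} = \sum_a \sum_b a^j b^k f(a,b)\) with 1-based row
  and column indices. 1-based indexing matters: with 0-based indices the
  first row and column would not contribute and the centroid
  \(\bar a = A_{10}/A_{00}\) would lose its meaning.
* **Central moments**: the same sums about the centroid
  \((\bar a, \bar b) = (A_{10}/A_{00}, A_{01}/A_{00})\). By construction
  \(\mu_{00} = A_{00}\) and \(\mu_{10} = \mu_{01} = 0\); both identities are
  asserted in the test suite.
* **Hahn moments**: the projection of the matrix onto weighted discrete
  orthogonal Hahn polynomials, \(H_{uv} = \sum_b \sum_a \beta_{ab}
  \tilde h_u(b)\tilde h_v(a)\) with 0-based sample index.

Raw moments are origin-referenced, central moments are location-invariant,
and Hahn moments are the orthogonal family — with a complete basis the Hahn
transform is invertible, so compositional and positional information is
provably conserved. Scale-invariant moment families are deliberately not
used: sequence "scale" carries signal here.

## The Hahn basis: definition and numerics

We use the classical Hahn polynomials \(Q_m(i;\alpha,\beta,N-1)\) with shape
parameters \((\alpha, \beta) = (y, x)\) on the integer grid
\(i = 0,\dots,N-1\), evaluated through the terminating \({}_3F_2\) series by
a term-ratio recurrence, together with their textbook orthogonality weight

\[\rho(i) \propto \frac{\Gamma(y+i+1)\,\Gamma(x+N-i)}{\Gamma(i+1)\,\Gamma(N-i)}.\]

The weight is computed in log-Gamma space (at N = 64 with positive shape
parameters the Gamma factors overflow double precision long before the
weighted values do) and rescaled so its maximum is 1 — any constant factor
cancels in the weighting. The square norm \(k_m^2\) of each degree is then
evaluated *numerically* as \(\sum_i Q_m(i)^2 \rho(i)\), and the stored basis
rows are \(\tilde h_m(i) = Q_m(i)\sqrt{\rho(i)/k_m^2}\). Because the weight
is the exact orthogonality weight of this family, the rows come out
orthonormal to machine precision; the test suite checks
\(|\langle \tilde h_m, \tilde h_n\rangle - \delta_{mn}| < 10^{-8}\) for
N ∈ {2, 4, 15, 16, 64} at x = y = 0 and x = y = 1, and full-basis
reconstruction to the same tolerance for N ≤ 8.

This definition was a genuinely open design point: the polynomial expression
this feature family is usually quoted with is not internally consistent as a
(polynomial, weight) pair — no positive weight orthogonalises it as written,
and its "square norm" is never defined. We resolved it by the classical
pair above, which coincides with the quoted family at the points where the
latter is unambiguous (degree 0 is identically 1; degree 1 is linear with
the same sign structure) and reduces at x = y = 0 to the discrete Chebyshev
polynomials under the uniform weight. Defaults are x = y = 0; both are
exposed in `sfv_config()` because nothing in the method fixes them.

Two further numerical choices: an all-zero matrix (possible only for
degenerate input) returns zero moment vectors with a warning rather than an
error, and for matrices smaller than 4×4 the Hahn degrees that do not exist
(m > N−1) are reported as zeros so the SFV layout stays fixed.

## Position-relative incidence matrices (PRIM / RPRIM, 60 values)

The PRIM captures where residues sit relative to one another. For symbols
x, y in the (k-mer) alphabet, with overlapping tokens at 1-based positions
and \(f(x)\) the position of the first occurrence of x,

\[\mathrm{PRIM}(x, y) = \sum_{p \,\in\, \mathrm{occ}(y)} \bigl(p - f(x)\bigr),\]

and rows for absent symbols are zero. The rule uses *all* occurrences of
the target, is position-sensitive, and keeps the sign of the offset, so
upstream and downstream placements are distinguished. For "AACG" the A-row
is (1, 2, 3, 0) and the C-row is (−3, 0, 1, 0); these and other worked
examples are frozen in `worked_examples()`. The reverse-direction matrix
(RPRIM) applies the identical rule to the reversed sequence, which is *not*
redundant: the first-occurrence reference breaks the symmetry.

The SFV uses the order-1 (4×4) matrices only, 30 moments each for forward
and reverse, with the Hahn basis at N = 4. Order-2 (16×16) and order-3
(64×64) matrices are available through `prim_matrix()` and
`prim_heatmap_table()` for dataset-level composition heatmaps; folding their
moments into the SFV would change its dimensionality and is deliberately not
done by default.

## Positional vectors (12 values)

* **FDV**: raw counts of A, C, G, T (sum = sequence length). Raw, not
  normalised, because the rest of the SFV also mixes unnormalised
  quantities; `fdv(seq, normalize = TRUE)` exists for visualisation.
* **AAPIV**: per-base sums of 1-based occurrence positions
  (components sum to n(n+1)/2 — every position counted once).
* **RAAPIV**: AAPIV of the reversed sequence.

## SFV layout

`seq_moments[30] ‖ prim_moments[30] ‖ rprim_moments[30] ‖ fdv[4] ‖
aapiv[4] ‖ raapiv[4]` — boundaries (30, 60, 90, 94, 98, 102) are exposed by
`sfv_block_bounds()` and asserted in tests. Extraction provenance (encoding
map, Hahn parameters, package version) travels in the feature-table header,
because the encoding is the single most consequential convention in the
whole pipeline: every numeric-moment value depends on it.

# The classifier

Both layers are random forests (bagged trees with random feature subsetting,
`mtry = ⌊√102⌋ = 10`, the classification default — trees are scale-equivariant,
so no feature standardisation is applied). Defaults: 100 trees, seeded.
Layer 2 is trained on true enhancers with known strong/weak labels only, not
on layer-1 predictions, matching how such benchmarks are constructed; rows
with unknown strength are excluded with a warning.

* **OOB error** is recorded at fit time; `oob_curve()` reads the error at
  each tree count from a single growing forest, which is how one verifies
  the error stabilises near 100 trees.
* **`tune_n_estimators()`** searches the 5–500 range by successive halving:
  candidates are spread geometrically, each rung evaluates survivors by OOB
  error on a stratified data fraction that doubles per rung, and the worse
  half is eliminated (ties break towards fewer trees). The budget and
  halving factor (2) are our defaults; the method itself does not fix them.
* **Prediction** offers the layers separately (the standard reporting
  convention) or as a cascade (layer 2 consulted only when the layer-1 vote
  fraction ≥ 0.5), an optional mode, off by default. Scores are class-vote
  fractions in [0, 1].

# Evaluation

`compute_metrics()` implements Sn, Sp, Acc and MCC from the confusion
counts; `metrics_chou()` implements the equivalent intuitive formulation in
terms of class totals and the two error counts, and the two are required to
agree to 1e-12 whenever both are defined. Zero denominators yield an
explicit `NA` sentinel — except MCC, where a degenerate table conventionally
scores 0. All internal values are fractions; percent formatting belongs to
the reporting layer.

`cross_validate()` uses *stratified* seeded folds (lower variance on
balanced data than plain random folds) and pools the held-out predictions
into one confusion matrix for the headline metrics — pooling is
deterministic given the fold assignment and matches single-table reporting;
per-fold metrics are kept for dispersion. `k = "loo"` gives the jackknife.
ROC/AUC and PR/AUPR are computed by an explicit threshold sweep (trapezoid
rule for AUC, step-wise recall summation for AUPR); the AUC is verified in
the tests against the Mann–Whitney pair statistic and an independent
library implementation.

# The synthetic generator

`simulate_dataset()` draws sequences i.i.d. per position: non-enhancers
uniform (0.25 per base); enhancers shift probability mass towards G and C
by `effect`/4 per base (GC-rich regulatory signal is the simplest realistic
proxy for enhancer-like composition; the direction is arbitrary and only
the magnitude matters to the tests); strong and weak enhancers sit at
`effect`/4 ± `effect`/16, a difference of `effect`/8, with shifts clamped so
probabilities stay in [0, 0.5] (the clamp binds only for the strong class at
`effect` > 8/9). Defaults mirror the benchmark shape this package targets:
1484 sequences per layer-1 class, an even 742/742 strong/weak split, 200 bp.

What the generator emulates: class-specific base composition, balanced
two-layer label structure, arbitrary-header FASTA organisation. What it does
not: motif structure, positional dependence along the window, homology
between sequences, chromatin-state or histone-mark correlations, and the
redundancy filtering applied to real benchmarks. Passing tests on this
generator therefore demonstrate that the pipeline recovers *compositional*
class separation end to end — it says nothing about performance on real
enhancer benchmarks, which must be evaluated on the real sequence sets.

```{r generator, eval = FALSE}
ds <- simulate_dataset(simulation_spec(n_enhancer = 200, n_non_enhancer = 200,
                                       effect = 1, seed = 42))
tab <- extract_dataset(ds)
cross_validate(tab, layer = 1, k = 5, config = forest_config(seed = 42))
```

At `effect = 1` (disjoint supports: enhancers have no A/T at the strong
extreme) pooled 5-fold layer-1 accuracy is ≥ 0.9 by a wide margin; at
`effect = 0` all classes are the same distribution and accuracy stays within
three binomial standard errors of 0.5. Both properties are asserted in the
acceptance tests at exactly those settings (n = 200 per class), and the
test suite elsewhere uses 60-sequence-per-class fixtures — sizes chosen so
the full suite exercises every stage, including two-layer cross-validation,
at desk scale.

# Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `encoding` | `sfv_config()` | A=1, C=2, G=3, T=4 | residue→integer map; alphabetical listing order |
| `hahn_x`, `hahn_y` | `sfv_config()` | 0, 0 | Hahn shape parameters (dimensionless) |
| `normalize_fdv` | `sfv_config()` | `FALSE` | divide composition counts by length |
| `n_trees` | `forest_config()` | 100 | trees per forest |
| `search_space` | `forest_config()` | 5–500 | tuning range for the tree count |
| `seed` | `forest_config()`, `simulation_spec()` | 7 | reproducibility |
| `effect` | `simulation_spec()` | 0.5 | compositional divergence in [0, 1] |
| `length` | `simulation_spec()` | 200 bp | window width |

# Known limitations

* Feature extraction is plain R; at benchmark scale (≈3000 sequences) it
  takes a few seconds, which is fine for the intended use but not for
  genome-wide scans.
* The strict A/C/G/T alphabet rejects ambiguity codes; `skip_invalid`
  drops such records rather than imputing them.
* The 0.5 vote threshold in cascade mode is not calibrated; per-layer
  evaluation is the primary interface.
* Heterogeneous sequence lengths are accepted (the reshape adapts per
  sequence) but make moment features less comparable across sequences; the
  loader warns when it sees them.
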