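---
title: "Methods: group analysis of streamline-count brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group analysis of streamline-count brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strucnet analyzes cohorts of structural brain networks in which each subject
is an N x N symmetric matrix of streamline counts (fiber number, FN) between
parcellated regions, together with group labels, demographic covariates and
clinical scores. This vignette documents the models and procedures, the
parameters that matter, the design choices made where the methodology is
genuinely underdetermined, and the limits of what the synthetic validation
shows.

## Connectivity matrices

A valid matrix is symmetric, nonnegative, finite, and zero on the diagonal.
Files are dense delimited text; asymmetries up to 1e-8 are repaired by
averaging, anything larger is rejected naming the worst cell — tractography
counters are integers, so a real asymmetry signals a corrupt file, not a
rounding artifact. Streamlines are counted once per unordered region pair
(counting per direction would only rescale all weights by two), and
streamlines with both endpoints in one region are discarded and tallied.
Node indices are 1-based in all files and reports, following atlas
convention. Fiber-number thresholds `w_min` zero out edges with counts
*strictly* below the threshold, so `w_min = 1` keeps every nonzero edge and
the default sweep 1..5 reproduces the usual stability analysis.

## Weighted graph metrics

Edge lengths are reciprocal weights, `l_ij = 1/w_ij`: stronger connections
are shorter. This is the one mapping under which raw-count networks produce
global efficiencies in the tens alongside path lengths of a few times
10^-2, the magnitudes typical of FN-weighted 90-node networks; the package
treats it as fixed.

* Strength `S_p` is the *mean* nodal strength `(1/N) Σ_i Σ_j w_ij`. Mean
  versus sum is a pure scale choice (factor N); the mean is implemented
  because it keeps `S_p` on the scale of a single region's connectivity.
* `E_glob = (1/(N(N−1))) Σ_{i≠j} 1/d_ij`, with disconnected pairs
  contributing zero.
* `L_p` is the mean shortest-path distance over *connected* ordered pairs
  only; the number of excluded pairs is reported alongside. Averaging
  infinities is useless and harmonic-mean conventions change the metric's
  identity, so exclusion-with-disclosure is the least-assumption choice.
* `C_p` is the Onnela weighted clustering coefficient with weights rescaled
  by the network-wide maximum, averaged over all nodes (degree < 2 nodes
  contribute 0). This variant is bounded in [0, 1] and is the common
  toolkit default among the several weighted clustering definitions in use.
* `E_loc` averages, over nodes, the global efficiency of the subgraph
  induced by each node's neighbors, keeping original weights.
* Small-world ratios divide `L_p` and `C_p` by their means over `n_random`
  surrogates (default 100) that preserve the degree sequence exactly —
  10 x |E| attempted degree-preserving edge swaps — and then permute the
  original weight multiset over the surviving edges. The literature rarely
  states its null recipe; this one preserves binary degree and the weight
  distribution, the two properties the ratios are meant to control for.
  `σ = γ/λ` holds exactly by construction, and the ensemble is seeded, so
  results are reproducible.

Degenerate inputs: an all-zero matrix is a validation error for global
metrics; isolated nodes get zero nodal efficiencies rather than errors.

## Group statistics

Group inference follows the standard neuroimaging ANCOVA pattern: the
omnibus test compares the linear model {group + covariates} against
{covariates only} by F-test, which with no covariates reduces exactly to
one-way ANOVA; pairwise contrasts are the t statistic of a group indicator
in a two-group GLM. Sex enters as a binary indicator. Two-sided p-values
throughout. For nodal metrics, Benjamini–Hochberg FDR runs across the N
regions *within* each metric family (global efficiency and local efficiency
corrected separately) — the joint-versus-separate choice is not dictated by
the methodology, and per-family correction matches how such results are
reported region-by-region per measure. Global metrics are reported
unadjusted (a handful of tests, conventionally taken at α = 0.05).
Partial correlations are Pearson correlations of covariate-residualized
vectors with p from the t transform on n − k − 2 degrees of freedom.
Untestable nodes (zero variance across subjects, e.g. isolated in every
subject) are reported as NA and excluded from the FDR denominator.

## Network-based statistic

Edges admitted to testing must be nonzero in at least 50% of the compared
subjects (configurable): edges that are mostly zeros yield unstable t
statistics and would only add noise components. Edge weights are
residualized on covariates once, across the pooled subjects of the pair;
the observed statistic is a pooled-variance two-sample t per edge, and the
primary threshold is specified as an edgewise two-sided p (default 0.01)
converted to the matching |t| quantile on n − 2 degrees of freedom.
Permutations shuffle the residual rows between groups (Freedman–Lane
ordering: covariates are removed *before* permutation), recomputing the
maximal suprathreshold component size each time; a component's corrected
p-value is `(1 + #{null ≥ observed}) / (1 + n_perm)`, which is strictly
positive and valid at finite permutation counts. The default 5,000
permutations match standard practice; calibration tests use 500. Zero
residual variance at an edge sets its t to 0 with a tally rather than
failing. The primary threshold and tail convention are deliberately
configurable because published analyses frequently omit them; the default
is two-sided.

For ROC analysis, a subject's component strength is the *mean* (not sum) of
their weights over the component's edges — mean keeps the score comparable
across components of different sizes; sum is a monotone transform with
identical AUC for a fixed component.

## Backbone, hubs, rich-club decomposition

The group backbone keeps edges present in strictly more than the
consistency fraction (default 0.8) of the group's subjects. Hubs are nodes
whose backbone degree exceeds mean + one *sample* (n−1) standard deviation;
sample versus population sd is not dictated anywhere, and the sample form
is R's default. Edge classes (rich-club / feeder / local by hub endpoints)
partition the backbone, and per-subject class strengths are sums of the
subject's weights over each class, so the three strengths always add to the
subject's backbone-restricted total strength. Group comparisons use each
group's own backbone by default, mirroring per-group construction; a pooled
backbone is available for sensitivity analysis. A second construction —
binarizing the group-mean matrix at a fixed sparsity (default 10%), ties at
the cutoff broken by the deterministic row-major edge order — is provided
for hub visualization; the consistency backbone is the default for
inference because it has a per-subject presence interpretation rather than
a group-average one.

## Classification

Features are the vectorized upper-triangle edge weights. Per training fold,
features are ranked by F-score — between-class mean separation over summed
within-class sample variances; zero-denominator features get F = 0 and a
flag, ranking last — and the top fraction is kept (rounded half-up, minimum
one feature). The SVM uses the radial kernel `exp(−g‖x−z‖²)` with `C = 1`
and `g` = 1/#selected features, the libsvm default convention. A printed
form of this kernel without the negation in the exponent circulates in the
applied literature; it diverges with distance and cannot be what any
working implementation computes, so the standard decaying kernel is
implemented. Features are standardized inside the SVM (the e1071 default):
streamline counts live on scales of tens to hundreds, where an unscaled
RBF with g ≈ 1/4005 is numerically degenerate (all off-diagonal kernel
entries ≈ 0).

The feature-fraction grid is 1%–20% in 1% steps. Two modes:

* `nested` (default): the fraction is chosen per outer fold by an inner
  leave-one-out loop on the training subjects; the test subject provably
  never influences ranking or fraction choice (an audit log records the
  subjects used at every fold, and the tests assert the exclusion).
* `paper`: one outer LOOCV per grid point, reporting the fraction that
  maximizes outer accuracy. This is the procedure most published
  connectome-SVM studies describe; it is optimistically biased, and the
  result object carries a warning flag saying so. The pipeline default is
  this mode because the pipeline is a study replica; switch to `nested`
  for honest generalization estimates.

The positive class is the clinically worse group of each pair, so
sensitivity is the patient-detection rate. AUC equals the Mann–Whitney
probability with ties counted one half.

## Synthetic cohorts: what they do and do not emulate

The generator reproduces the *statistical design* of a three-group clinical
DTI study: 26 converters, 26 non-converters, 26 controls over 90 nodes by
default; age uniform on 50–78 years, balanced sex, education uniform on
0–20 years, matching the demographic ranges of such cohorts.

* **Template.** A connected graph at density 0.15 (~600 of 4,005 possible
  edges, the typical sparsity of deterministic-tractography networks) built
  by preferential attachment, giving a right-skewed degree distribution
  with a minority of hubs; mean weights (scale 50 streamlines) decay with
  node-index distance as a crude geometry proxy.
* **Subject weights.** Negative binomial around the template means
  (dispersion `size = 8`): streamline counts are overdispersed nonnegative
  integers, and Poisson variance is far too tight for between-subject
  variability.
* **Planted effect.** A connected edge set grown from a high-degree node
  (150 edges, ~25% of the template, by default) multiplied by 0.6 in
  converters and 0.8 in non-converters. The plant is connected and
  hub-seeded so NBS recovery is meaningful; its default size is large
  because empirical converter cohorts show diffuse strength reductions on
  the order of 15–20%, which a small plant cannot produce. Focused
  recovery simulations use a 30-edge plant instead.
* **Covariates.** Log-linear multiplicative effects on edge weights
  (age −0.005/yr, sex 0.05, education 0.005/yr, centered), keeping weights
  nonnegative and making linear residualization approximately correct —
  which is exactly the assumption the analysis pipeline makes.
* **Clinical scores.** MMSE/MoCA/AVLT-like scores are linear in the
  subject's realized global efficiency plus Gaussian noise, with group
  offsets ordered control > non-converter > converter. The slope (5 points
  per cohort SD of efficiency) and noise (SD 1.3) were fixed by a power
  calculation: the within-group covariate-residualized spread of efficiency
  is about a quarter of the cohort SD, so these values give within-group
  correlations near 0.7, recoverable at n = 26 with ~98% power. This
  deliberately favors recoverability over realism — empirical
  metric–score correlations around 0.45 would be detected only ~60% of the
  time at this sample size, which would make parameter-recovery tests
  uninformative.

What the generator does **not** emulate: spatial geometry and hemispheric
symmetry of real parcellations; tractography error structure (distance
bias, crossing-fiber dropout); and — importantly — the high transitivity of
real white-matter networks. Synthetic templates have γ near 1 (they are
their own degree-matched null), whereas empirical FN networks show γ ≈ 3.
Passing tests therefore validate the *statistical machinery* (calibration,
recovery, error control), not the topological realism of the inputs; the
small-world code is instead validated on ring lattices (γ > 1) and
Erdős–Rényi-like graphs (σ ≈ 1), where ground truth is known.

## Reproducibility and problem sizes

Every stochastic stage derives its seed from the global seed and the stage
name (`derive_seed`), so pipeline reruns are byte-identical and stages can
be reproduced in isolation. Validation simulations use sizes chosen to make
their statistical claims sharp while staying desk-runnable: metric oracles
on 50 random graphs of up to 12 nodes against brute-force definitional
implementations (tolerance 1e-10); NBS family-wise error on 200 null
cohorts of 2 x 20 subjects over 30 nodes at 500 permutations, judged
against the exact binomial 95% interval; recovery on 50 cohorts of
2 x 26 subjects over 90 nodes with a 30-edge plant at 0.5x; effect-direction
and score-correlation recovery on 100 cohorts at the full default design.

## Known limitations

* The NBS residualizes covariates once on the pooled pair (Freedman–Lane
  style); exactness holds only asymptotically under non-exchangeable
  covariate designs.
* The primary-threshold t quantile uses n − 2 degrees of freedom, ignoring
  the covariate degrees spent in residualization; with 3 covariates and
  ~50 subjects the difference is cosmetic, and the threshold is a
  cluster-defining device, not an inferential claim.
* `paper`-mode classification accuracy is optimistically biased by
  construction; it exists for comparability with the published procedure.
* Backbone hub sets can be empty (constant degree), which downgrades all
  edges to "local" with a warning rather than failing.
* The generator's clinical-score calibration is stronger than typical
  empirical effect sizes (see above); treat recovered correlations as a
  machinery check, not an effect-size forecast.
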