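# strucnet

Group-level analysis of structural brain connectomes, for researchers who
study white-matter network alterations in clinical cohorts — for example
amnestic mild cognitive impairment (aMCI) patients who later convert to
Alzheimer's disease versus those who remain stable and matched healthy
controls.

The unit of analysis is a per-subject N x N symmetric connectivity matrix
whose entries are streamline counts (fiber number, FN) between parcellated
gray-matter regions (e.g. the 90-region AAL atlas). On top of this the
package provides the full analysis chain such a study needs:

- **Weighted graph metrics.** Network strength `S_p = (1/N) Σ_i s(i)`,
  global efficiency `E_glob = (1/(N(N−1))) Σ_{i≠j} 1/d_ij`, local efficiency
  (mean efficiency of each node's neighbor subgraph), characteristic path
  length `L_p`, Onnela weighted clustering `C_p`, with edge lengths `1/w`.
  Small-world ratios `λ = L_p/⟨L_p^rand⟩`, `γ = C_p/⟨C_p^rand⟩`,
  `σ = γ/λ` are normalized against degree-preserving rewired surrogates with
  reshuffled weights.
- **Covariate-adjusted group statistics.** ANCOVA omnibus F-tests and
  pairwise GLM contrasts adjusting for age, sex and education;
  Benjamini–Hochberg FDR across regions for nodal metrics; partial
  correlations between network metrics and clinical scores (MMSE, MoCA,
  AVLT).
- **Network-based statistic (NBS).** Connected components of edges whose
  covariate-adjusted two-sample |t| exceeds a primary threshold, with
  family-wise-corrected p-values from the permutation null of the maximal
  component size.
- **Rich-club decomposition.** Group backbone networks (edges present in
  over 80% of subjects), hubs by `K(i) > mean(K) + sd(K)`, edges classed as
  rich-club (hub–hub), feeder (hub–nonhub) or local (nonhub–nonhub), with
  per-subject class strengths.
- **Classification.** F-score-ranked edge features,
  `F(i) = [(x̄_i⁺−x̄_i)² + (x̄_i⁻−x̄_i)²] / [s²₊ + s²₋]`, feeding an RBF SVM
  (`C = 1`, kernel width = 1/#features) under leave-one-out
  cross-validation with a 1–20% feature-fraction grid, plus ROC/AUC by the
  Mann–Whitney statistic.
- **Synthetic cohorts.** A generator that emulates the three-group study
  design — hub-bearing templates, negative-binomial streamline counts, a
  planted weakened component in the converter group, log-linear covariate
  effects, efficiency-linked clinical scores — so the whole pipeline is
  testable with known ground truth.

## Worked example

```r
library(strucnet)

cfg <- synthetic_config(n_nodes = 40,
                        group_sizes = c(converter = 12, nonconverter = 12,
                                        control = 12),
                        planted_edges = 40, seed = 7)
cohort <- sample_cohort(cfg)

gm <- global_metrics(cohort$matrices[[1]], n_random = 10, seed = 1)
print(gm)
#> global network metrics: Sp=264.4 Eglob=25.5 Eloc=16.24 Lp=0.0495 Cp=0.07744
#>   small-world (n_random=10): lambda=0.942 gamma=0.936 sigma=0.994

nbs <- nbs_test(cohort, c("converter", "control"), n_perm = 200, seed = 3)
print(nbs)
#> NBS: converter vs control, primary p < 0.01 (|t| > 2.82, two-sided), 200 permutations
#>   117 admitted edges; 2 suprathreshold component(s)
#>   component 1: 26 edges, 23 nodes, corrected p = 0.004975
#>   component 2: 1 edges, 2 nodes, corrected p = 0.6517
```

`Sp` is the mean regional strength (streamline counts), `Eglob`/`Eloc` are
integration/segregation efficiencies on `1/w` edge lengths, and `sigma ≈ 1`
says this synthetic network is no more clustered than its degree-matched
random surrogates. The NBS finds one family-wise significant component
(corrected p ≈ 0.005) of 26 edges — most of the 40-edge component planted at
weight ratio 0.6 in converters — while the stray single-edge component is
correctly non-significant.

The full study replica — metrics, group ANCOVAs, NBS for all pairs, ROC of
component strengths, rich-club strengths, SVM classification, and a
fiber-threshold (w_min = 1..5) stability sweep — runs as

```r
report <- run_pipeline(synthetic_config(seed = 1), seed = 1,
                       out_dir = "results")
print(report)
```

A thin command-line wrapper with `simulate/metrics/compare/nbs/richclub/
classify/roc/run` subcommands lives at `inst/cli/strucnet.R`.

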