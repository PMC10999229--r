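---
title: "Methods: Betti-0 filtration curves, segregation, and the longitudinal inference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Betti-0 filtration curves, segregation, and the longitudinal inference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
`phconnect`, in the order data flows through the package.

## Connectivity matrices

A participant's data enter as a node-by-time matrix. Edges are Pearson
correlations over all node pairs, Fisher-transformed (`z = atanh(r)`) for
variance stabilization. Because synthetic or degenerate data can produce
`|r| = 1`, correlations are clipped to `1 - 1e-7` in absolute value before
`atanh`; for real-valued data this clip is inert. The diagonal is stored as
zero and excluded from every downstream computation; a constant node series
or fewer than three samples is an error, not a silent NA.

## Edge-density filtration and the Betti-0 curve

The filtration parameter is the edge-density fraction ε. At ε the retained
graph consists of the top `ceiling(ε * E)` edges of the descending weight
ranking over the `E = n(n-1)/2` unique pairs, and B₀(ε) is its number of
connected components (union-find with path compression and union by size,
compiled; a breadth-first-search component count is the independent oracle
in the tests). Conventions worth stating explicitly:

* **Rank-set retention.** The retained set at ε is defined as the
  top-`⌈ε·E⌉` *ranked* edges, with ties broken by node-index order. An
  equivalent phrasing — "edges strictly above the cutoff weight W" —
  differs by exactly the rank-`⌈ε·E⌉` edge when weights are distinct; the
  rank-set definition is the one that makes "the top 1% of edges" mean
  literally that, and ties are measure-zero for real connectivity data.
* **Grid.** ε runs over `0, step, 2·step, ...` with `step = 0.01` by
  default (one percentile of the edge-weight distribution per step). The
  retained-rank computation subtracts `1e-9` before `ceiling` so that
  mathematically integral products such as `0.4 × 15` do not round up.
* **Stopping.** The curve starts at `(0, n)` and stops at the first grid
  point with B₀ = 1. Negative-weight edges enter the retained set only if a
  single component has not formed before their ranks are reached; if B₀
  never reaches 1 the curve ends at density 1 with a `truncated` flag.
* **AUC.** The trapezoidal integral of B₀ against ε over the stored curve.
  The x-axis is the density fraction, so a step contributes width 0.01
  regardless of the weight scale — AUC is therefore invariant under any
  rank-preserving transform of the weights (Fisher z versus raw r, or a
  constant shift), which the tests assert.
* **Correlation mode.** A variant filtration uses descending correlation
  cutoffs in steps of 0.01, stored against `1 - r` so thresholds ascend.
  It is *not* shift-invariant (by design). One monotonicity property holds
  only here: raising a single edge weight can never increase the AUC under
  a correlation cutoff, because each retained set can only gain the
  promoted edge. Under density filtration this is false in general — the
  promoted edge displaces the previous rank-k edge from every top-k set,
  which can delay a merge — so the property test runs in correlation mode.

## System segregation and modularity Q

Both comparators use the positive-part matrix (negative Fisher-z weights set
to zero). Segregation for a node-to-network partition is

`(mean Z_within − mean Z_between) / mean Z_within`,

with the means taken over *all* within- and between-network pairs: zeroed
edges stay in the denominator counts by default, matching the convention of
zeroing (not deleting) negative edges. `include_zeros = FALSE` restricts the
means to strictly positive edges for sensitivity analyses. A non-positive
within-network mean makes the normalization meaningless and is an error.

Modularity Q is Newman's weighted modularity. The maximization must be
deterministic — a single Q per matrix — so the package uses: recursive
leading-eigenvector bisection of the generalized modularity matrix with
Kernighan–Lin fine-tuning after each split; a Kernighan–Lin-style
full-partition refinement (each pass tentatively moves every node once to
its best alternative community, allowing downhill moves, and keeps the best
prefix) alternated with pairwise community merges and spectral re-splits;
and a portfolio of deterministic starts (the spectral partition, greedy
agglomerative merging, and the sign patterns of the top two and three
eigenvectors), the best final Q winning. Acceptance anchors the result to a
brute-force search over all set partitions on graphs of up to 8 nodes.
Community detection here is agnostic to the a priori network partition.

## The inference chain

* **Behavior standardization.** z-scores use the baseline mean and SD of
  each task across participants; follow-up scores use the *baseline*
  statistics, so their mean is not zero in general. Reaction-time domains
  are sign-inverted so higher always means better.
* **Change scores.** Follow-up minus baseline, residualized on baseline by
  OLS. This is applied to every factor measured at both timepoints —
  brain measures, behavior, cortical thickness and WMH volume alike (the
  treatment of the covariate changes is an interpretation; it is applied
  uniformly and documented here).
* **Scrubbing.** The per-domain mean scrubbing fraction is regressed out of
  each functional brain measure (AUC, segregation, Q) before modeling; it
  is not removed from behavior or from the structural covariates.
* **Models.** OLS with listwise deletion per model. Reported per
  predictor: standardized beta `b·SD(x)/SD(y)`, the raw-coefficient
  t-based 95% CI (the CI is deliberately on the raw scale), p, and partial
  eta-squared computed as `t²/(t² + residual df)`, which equals
  SS_effect/(SS_effect+SS_error) for a single-df term.
* **FDR families.** Per cognitive domain, the p-values of all predictors
  from all models are concatenated — 2 brain measures × 3 time contrasts ×
  6 predictors plus 2 behavior variants × 3 contrasts × 7 predictors = 78 —
  and Benjamini–Hochberg adjusted as one family. The 78-way composition is
  asserted by the tests.
* **Permutation test.** Rows of the full predictor block are permuted
  jointly against the outcome, preserving within-participant predictor
  assignment. The statistic is the absolute standardized beta of the target
  predictor, and `p = #(null ≥ observed) / n_perm` — the literal ratio, so
  the minimum attainable p is 0; a `plus_one` flag enables the
  `(count+1)/(N+1)` correction but defaults off.
* **Mediation.** Three nested OLS fits give path a (`m ~ x + cov`), paths
  c′ and b (`y ~ x + m + cov`) and the total effect (`y ~ x + cov`);
  ACME = a·b, which equals total − direct exactly for OLS on common cases
  (asserted to 1e-10). Participants are resampled as whole rows; CIs are
  percentile intervals and the bootstrap p is twice the smaller tail
  fraction of the distribution around zero (a two-sided percentile
  convention, stated here because several conventions exist).
* **BIC search.** Every non-empty subset of the candidate predictors is fit
  on the common complete cases (so BICs are comparable), under the Gaussian
  likelihood with the variance profiled out; 7 candidates give 127 models.

## The synthetic cohort generator

The generator produces the minimal data-generating process the analysis
chain assumes, not a simulation of fMRI physics.

* **Connectivity.** Node signals follow a factor model:
  `x = w·f_community + b·g_global + noise`, all factors unit-variance
  Gaussian. For long series, within-community correlations approach
  `(w² + b²)/(w² + b² + 1)` and between-community correlations
  `b²/(w² + b² + 1)` — the closed form the tests verify by Monte Carlo.
  Defaults `w = 0.5`, `b = 0.15` give within-r ≈ 0.22 and between-r ≈ 0.02,
  a modular but not caricatured structure.
* **Parcellation.** `simulate_partition()` splits n nodes into as-equal
  communities (264 nodes, 14 networks by default; the remainder goes to the
  first networks in label order, deterministically).
* **Aging.** At follow-up the within-coupling shifts by
  `seg_decline_slope · (age − midpoint(age_range))` plus an idiosyncratic
  offset with SD `coupling_sd`. The midpoint (50 years for the default
  20–80 range) is used rather than the sample mean so each participant's
  truth is independent of the rest of the cohort. The default slope
  −0.004/yr makes a 30-year age gap worth −0.12 in coupling.
* **Heterogeneity is essential, not decorative.** Without `coupling_sd`
  the latent coupling change would be an exact linear function of age, and
  no regression could separate the topology change from age itself — the
  confirmatory coefficient of ΔAUC conditional on Age would be estimating
  pure noise. The default 0.08 makes the idiosyncratic component equal in
  magnitude to the age-graded component (0.004 × SD(age) ≈ 0.07), a split
  chosen by a pre-study power calculation so that the programmed effects
  are recoverable with high probability at the cohort sizes used in the
  recovery experiments; it was fixed before those experiments were frozen.
* **Behavior.** The change in behavior, in baseline-SD units, is
  `beta_age_behavior·(age − 50) + beta_auc_behavior·Δcoupling +
  beta_nart_behavior·(NART − 117) + noise`, mapped onto each domain's raw
  scale (percent-correct-like for accuracy domains, reaction-time-like and
  inverted for speed). Ages are uniform over the range — decade brackets in
  demographic tables are a reporting convenience, not a model. Covariates
  (sex, education, NART, scrubbing, cortical thickness, WMH) are drawn
  independently with realistic magnitudes; their empirical covariance is
  deliberately not modeled, and the package makes no claim that passing
  recovery tests implies correct behavior under correlated covariates.
* **Determinism.** A `sim_config()` seed fixes the cohort bit-for-bit,
  including per-participant series seeds drawn from the main stream.

What the generator does *not* emulate: scanner noise spectra, motion,
task-design structure in the time series, non-Gaussian behavioral
distributions, domain-to-domain correlation of decline, or the empirical
effect sizes of any real cohort. Recovery tests therefore demonstrate that
the pipeline estimates what it is pointed at — not that real data satisfy
the generator's assumptions.

## Problem sizes and runtime choices

The test suite and acceptance script run at sizes chosen to make the
statistical assertions meaningful while keeping runs short: oracle
equivalence on 20–40-node matrices; null calibration on cohorts of 60
participants, 30 nodes, 5 networks (200 seeds × 500 permutations);
recovery on cohorts of 160 participants, 60 nodes, 6 networks at the
fluid-task series length of 430 samples (100 seeds); mediation truth at
n = 2000. The full 264-node, 14-network scale is exercised for the
combinatorial checks (34,716 pairs; B₀(0) = 264), and nothing in the
implementation depends on the reduced sizes.

## Known limitations

* Only B₀ is computed; loops and voids (higher homology), barcodes and
  persistence diagrams are out of scope.
* Density-mode AUC is not monotone under single-edge promotion (see above);
  no claim of edgewise monotonicity should be attached to it.
* The modularity maximizer is a deterministic heuristic; exhaustive
  optimality is only guaranteed where the tests anchor it (small graphs),
  although the multi-start portfolio makes higher-dimensional failures
  rare.
* Listwise deletion mirrors the per-domain availability design; no
  imputation or mixed-effects alternative is offered.
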