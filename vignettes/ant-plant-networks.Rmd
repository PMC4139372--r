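---
title: "Methods: bipartite ant-plant networks and exclusion-experiment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite ant-plant networks and exclusion-experiment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnet)
```

`antnet` analyses facultative mutualisms between ants and plants bearing
extrafloral nectaries (EFNs) at the community scale. Its two halves mirror
the two ways such systems are studied: the *structure* of who-visits-whom
(bipartite network metrics with null-model inference) and the *outcome* of
the association for the plants (a factorial ant-exclusion herbivory
experiment). This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The incidence matrix

The central object is a labelled count matrix with ant species as rows and
plant species as columns. In the packaged Cerrado census
(`fixture_table1()`), cell `a_ij` counts the tagged individuals of plant
species *j* (30 per species) on which ant species *i* was recorded over two
field seasons, so every cell is bounded by 30 and column sums are bounded
by design, not biology. Descriptors follow the standard definitions:

- degree `k` — number of partner species with a positive count;
- connectance `C = 100·L/(I·J)` for `L` realized links among `I` plants and
  `J` ants;
- web asymmetry `W = (I−J)/(I+J)`, positive when plants outnumber ants.

Published summary tables in this field often print `|W|` and truncate at
two decimals (17/35 = 0.4857 appears as 0.48, not 0.49). `report_value(x,
"truncate2")` reproduces that convention; all internal arithmetic is full
precision, and `metric_report()` exposes both the signed and absolute
values so the truncation is an output format, never a data transformation.

## NODF nestedness and the Ce null model

NODF (Nestedness metric based on Overlap and Decreasing Fill) scores, for
every unordered pair of rows and of columns, `100·(shared presences)/(fill
of the less-filled member)` when the two fills strictly differ and 0
otherwise, and averages over all pairs. Two numerical choices matter:

- *equal fills contribute exactly zero* — the "decreasing fill" condition
  is strict, so a matrix of identical rows scores 0, not 100;
- *an empty less-filled line contributes zero* rather than 0/0.

Significance uses a Monte-Carlo ensemble under the probabilistic **Ce
(type II)** null: cell `(i, j)` is occupied independently with probability
`(k_i/C + k_j/R)/2`, the mean of the row's and column's fill proportions.
This null conserves the expected number of links exactly (the probabilities
sum to `L` algebraically) while letting the margins fluctuate. Draws with
empty rows or columns are *kept and scored* — discarding them would bias the
null toward nestedness; only fully empty draws (possible in principle for
tiny sparse matrices) are scored as zero and counted in
`n_degenerate_discarded` for transparency. The one-tailed p-value uses the
add-one rule `(1 + #{null ≥ obs})/(1 + n)` so that `p` is never zero and
1,000 randomizations can report at best `p < 0.001`. The default ensemble
size is 1,000, the classical choice; tests in this package use 50–500
draws, which keeps Monte-Carlo error well below the decision thresholds
they assert while keeping the default test run fast.

The implementation is vectorized (`tcrossprod` over row pairs); tests pin
it to an independent, deliberately naive O(R²C + C²R) double-loop oracle on
hundreds of random matrices up to 8×8, and to its permutation- and
transpose-invariance properties.

## H₂′ specialization

`H2 = −Σ p_ij ln p_ij` (natural log) is the two-dimensional Shannon entropy
of the interaction proportions `p_ij = a_ij/m`. Its extremes given the
observed marginal totals are:

- `H2max`: the entropy of the *continuous* independence table
  `r_i·c_j/m` — equivalently the sum of the two marginal entropies. An
  integer-constrained maximum would differ only at tiny grand totals; with
  `m` in the hundreds, as here, the difference is negligible, so the
  simpler continuous bound is used.
- `H2min`: a greedy concentration heuristic — repeatedly allocate
  `min(largest remaining row total, largest remaining column total)` to
  that cell, ties broken by lowest index. The greedy value can only
  over-estimate the true constrained minimum; tests enumerate *every*
  integer table at toy scale (`m ≤ 8`, up to 3×3) and verify both the bound
  direction and that the resulting index differs from the
  exhaustive-oracle value by < 0.05.

`H2' = (H2max − H2)/(H2max − H2min)`, clamped to [0, 1]; when the bounds
collapse (`H2max − H2min < 1e−9`, e.g. a single row), the index is defined
as 0 — with degenerate marginals there is nothing to specialize on. A
permutation-diagonal matrix scores 1; an integer independence table scores
0.

## Temporal comparison

`align_networks()` matches species by exact label (no fuzzy matching — a
census is expected to use consistent names), lists turnover, tabulates
per-species degree change with absent species scored as degree 0, and
compares the degree distributions of the two periods with a two-sample
Kolmogorov–Smirnov test. Degree samples are small and heavily tied, so `D`
is evaluated exactly on the pooled support, the asymptotic p-value is used
(ties make the exact one unavailable), and results carry an `approx` flag
when either sample has fewer than 10 values.

The packaged census distinguishes species seen in only one study year;
`fixture_year_network()` uses those lists to carve the 26-species (first
year) and 29-species (second year) assemblages out of the combined table.
The within-year interaction *counts* were never published, so these subsets
reproduce species composition and turnover exactly but carry combined-period
weights — per-year quantitative metrics (H₂′, per-year NODF values, the
published per-year KS statistics) are therefore not recomputable from the
printed data, and the package does not pretend otherwise.

## The exclusion experiment

The analysis unit is the stem-year mean of the nine tagged leaves
(`stem_mean_herbivory()`); leaf position is recorded but not modelled,
matching how such designs are analysed. Herbivory percentages are analysed
untransformed by default — grid-based leaf-loss indices at these levels are
close to normal — with an optional arcsine-square-root switch.

`factorial_anova()` fits the full fixed-effects species × stem × year
model. For balanced data the decomposition equals the textbook Type-I
ANOVA exactly (a test asserts this); for unbalanced data (field designs
lose leaves) it uses sum-to-zero contrasts with partial (Type-III) sums of
squares, the standard choice when main effects must be interpretable in
the presence of interactions. A constant response returns an all-zero
table with undefined F ratios rather than an error. The balanced design's
df structure is (8, 1, 1, 8, 8, 1, 8) with 1,044 error df at n = 30.

Post hoc machinery:

- `tukey_hsd()` works from cell means, the error mean square, its df and
  the group sizes (Tukey–Kramer allowance for unequal sizes), with
  adjusted p from the studentized range; it is cross-checked against
  `stats::TukeyHSD` on balanced data.
- `per_species_treatment_tests()` runs pooled-variance Student's t-tests
  (Welch by flag) of control vs excluded stems per species within year and
  Bonferroni-multiplies by the number of species tested *within that
  year* — the family matches per-year reporting; a paired option exists
  because field protocols sometimes pair stems within individuals.
- `paired_abundance_test()` compares `log(x+1)` ant counts between years,
  paired by plant individual, signed first-period-minus-second so more
  ants later gives negative t. Zero-variance differences return `t = 0,
  p = 1` (no shift) or a signed infinite t (pure shift) instead of an
  error.

## Synthetic data

The generators exist so that every pipeline stage is testable without any
field data, and their defaults are fixed at the study's conditions:

- `generate_network()`: 29 ants × 9 plants (the larger study year, inside
  the observed 26–31 band), target fill 0.5 (the observed 0.48–0.54),
  counts capped at 30 individuals per plant. Species totals follow a
  rank-power-law with exponent `marginal_skew` (default 1 — EFN visitor
  assemblages are strongly dominated by a few generalists); any target
  degree exceeding the axis length is capped with its excess redistributed
  so the expected link count stays on target. Cell probabilities
  interpolate between uniform-given-fill (`nested_strength = 0`) and the
  Ce form built from the skewed target degrees (`nested_strength = 1`,
  the default), so nestedness is induced through exactly the marginal
  heterogeneity the null-model family measures. A consequence worth
  stating plainly: a strength-1 network is a *typical draw* of the Ce
  family, so its Monte-Carlo p against the Ce null is stochastically small
  but not uniformly below 0.05; the package's tests assert the paired
  separation of the p distributions between strengths, and detection
  (p ≤ 0.05) on the real census matrix.
- `generate_herbivory()`: a balanced 9 species × 2 stems × 2 years design
  with 30 individuals, nine leaves per stem. Leaf herbivory (%) is
  additive — baseline 15, species effects with SD 5, +3 when ants are
  excluded, +4 in the second year, Gaussian stem noise SD 2 and leaf noise
  SD 1 — clamped to [0, 100]. Abundance is lognormal (meanlog log 20,
  sdlog 0.8) with a ×1.5 second-year multiplier. Effect sizes are the
  magnitudes the power analyses in the tests assume (treatment δ = 1.5×
  stem noise SD); the clamp is inactive at these defaults (15 ± a few SD
  stays far from both bounds) but protects extreme user configurations.

Both generators are pure functions of their arguments and seed
(Mersenne–Twister via `withr::with_seed`).

What the generators do *not* emulate: phenological covariation of nectar
secretion and ant activity, spatial structure among plants, overdispersed
or zero-inflated herbivory, observation error in the grid index, and
behavioural differences among ant species (all visits count equally).
Passing parameter-recovery tests on this synthetic world therefore shows
the estimators are correct and adequately powered under additive Gaussian
assumptions — not that those assumptions hold in any particular field
system.

## Determinism and problem sizes

`run_study()` fans one global seed out to fixed per-stage seeds (drawn
once by `sample.int`), so a full bundle is byte-reproducible and stages
can be re-run independently. The test suite sizes its simulations to run
in about a minute in total: the null-calibration suite refits the
factorial 1,000 times at 3 individuals per cell (108 stem means per fit),
parameter recovery uses 20–100 seeded replicates at full design size, and
null ensembles in tests use 50–500 draws; the shipped defaults (1,000
randomizations, 30 individuals) are what an analysis of real data should
use.

## Known limitations

- Per-year quantitative matrices, census-level association counts and raw
  leaf records of the packaged study are unpublished; everything derived
  from them is reproduced only at the level the printed data support
  (species sets, turnover, closed-form metrics, combined-matrix indices).
- The greedy `H2min` is a heuristic; it is provably an upper bound on the
  constrained minimum and exhaustively validated only at toy scale.
- The asymptotic KS p-value is approximate under heavy ties and small
  samples; the `approx` flag marks it.
- `H2'` on the *binary* matrix is not meaningful; the index needs counts.
- No modularity, species-level specialization (d′), weighted nestedness
  variants, or network drawing — deliberately out of scope.
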