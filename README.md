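# antnet

Bipartite ant–plant interaction networks and the outcome statistics of
ant-exclusion experiments, in tidyverse-flavoured R.

In tropical savannas, many trees bear extrafloral nectaries (EFNs) that
attract ants; the visiting ants can in turn deter herbivores. Ecologists
study these facultative mutualisms at the community scale with two tools
this package implements end to end:

1. **Bipartite network analysis** of an ant × plant incidence matrix
   `A = (a_ij)` — species degree *k*, connectance `C = 100·L/(I·J)`,
   web asymmetry `W = (I−J)/(I+J)`, nestedness (NODF, 0–100) with a
   Monte-Carlo significance test under the probabilistic **Ce (type II)
   null model** (`p_ij = (k_i/C + k_j/R)/2`), and the network-level
   specialization index **H₂′** — the two-dimensional Shannon entropy of
   interaction proportions rescaled between its constrained extremes given
   the marginal totals, 0 = extreme generalization, 1 = extreme
   specialization.
2. **Experimental outcome statistics** for a paired-stem ant-exclusion
   design: grid-based leaf herbivory indices, a species × stem-treatment ×
   year factorial ANOVA with Tukey post hoc comparisons, per-species
   t-tests with Bonferroni correction, and a paired t-test of log(x+1)
   ant abundance between years.

A two-year Cerrado field census (31 ant species on 9 EFN-bearing tree
species, 30 tagged individuals per species) ships as a plain-CSV fixture,
and seeded generators produce synthetic networks and herbivory experiments
with the same statistical structure, so every stage is testable offline.

## Worked example

```r
library(antnet)

m <- fixture_table1()
glance(m)
#> # A tibble: 1 × 6
#>   n_ants n_plants n_links n_associations  fill connectance_pct
#> 1     31        9     151            693 0.541            54.1

full_degree_species(m)   # ants recorded on every plant species
#> [1] "Brachymyrmex sp.1"  "Camponotus crassus"  "Camponotus blandus"
#> [4] "Cephalotes pusillus" "Pseudomyrmex gracilis" "Pseudomyrmex flavidulus"
#> [7] "Ectatomma tuberculatum"

metric_report(m, n_randomizations = 1000, seed = 1) |>
  dplyr::select(h2_prime, nodf, nodf_z, nodf_p)
#> # A tibble: 1 × 4
#>   h2_prime  nodf nodf_z nodf_p
#> 1   0.0995  66.7   1.88 0.0240
```

The census network is weakly specialized (H₂′ ≈ 0.10: ants spread their
visits close to what the marginal totals alone predict) and significantly
nested (observed NODF 66.7 sits above the Ce-null mean; one-tailed
Monte-Carlo P ≈ 0.02 at 1,000 randomizations) — the classic profile of
EFN-mediated mutualistic networks.

Comparing the two study years (species carved from the combined census by
the published single-year records):

```r
cmp <- align_networks(fixture_year_network("2009"), fixture_year_network("2010"))
glance(cmp)[, 1:4]
#> # A tibble: 1 × 4
#>   n_shared n_only_in_a n_only_in_b n_unchanged_degree
#> 1       24           2           5                 24
```

And a full synthetic pipeline run, exercising the factorial experiment:

```r
sim <- generate_herbivory(seed = 1)
res <- run_study(generate_network(seed = 1), generate_network(seed = 2),
                 sim$leaves, sim$abundance, n_randomizations = 200, seed = 3)
tidy(res$anova)[1:3, c("term", "df", "statistic", "p.value")]
#> # A tibble: 3 × 4
#>   term       df statistic   p.value
#> 1 species     8      664. 0
#> 2 stem        1      589. 1.38e-103
#> 3 year        1     1019. 1.51e-156
```

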