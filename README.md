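# beebreedsim

Stochastic simulation of a closed honeybee (*Apis mellifera*) breeding
program, for quantitative geneticists and breeding-scheme designers who
want to compare selection strategies and mating designs before running
them on real bees.

Honeybee breeding is hard to model with standard livestock machinery:
performance is measured on the colony, not the individual, and results
jointly from the *maternal* genetic effect of the queen and the *direct*
genetic effects of tens of thousands of workers; queens are diploid but
drones are haploid gametes of their mother; and queens may be inseminated
by one drone (monoandry) or many (polyandry). `beebreedsim` implements a
Monte Carlo simulator of a small closed breeding population under the
infinitesimal model:

```
P = BV_mat(queen) + mean BV_dir(workers) + e,        e ~ N(0, σ²_e)
BV(drone)    = ½ BV(DPQ) + φ(DPQ)                    (haploid dam gamete)
BV(daughter) = ½ BV(dam) + BV(sire drone) + φ(dam),  φ ~ N(0, ¼(1−F)Σ_BV)
σ²_P = σ²_mat + (n_D + 2)/(4 n_D) · σ²_dir + σ_dir,mat + σ²_e
```

Inbreeding `F` is tracked exactly with a haplodiploid numerator
relationship (coancestry) matrix built by the tabular method for
sex-chromosome inheritance, validated against gene-dropping. The annual
cycle covers reproduction (6 breeding queens × 60 daughters), fixed-count
winter mortality, phenotyping of 108 candidate colonies, mass or
within-maternal-line selection of breeding queens, two-step selection of
drone-producing queens (4 best sib groups, 3 best sisters each), and
mating with 1, 8 or 16 drones bred by a single drone-producing queen.

## Worked example

Twenty-three years of within-line selection with 8-drone polyandry,
genetic setup 1 (direct and maternal variances 10, no correlation,
residual variance 30), 40 replicates:

```r
library(beebreedsim)

spec <- scenario_spec(setup = 1, strategy = "L", n_drones = 8,
                      n_replicates = 40, years = 23)
res  <- run_scenario(spec, seed = 1)
standardize_endpoint(res)[, c("F_pct", "P_std", "bv_dir_std", "bv_mat_std")]
#>      F_pct    P_std bv_dir_std bv_mat_std
#> 1 19.60231 4.703956   4.642212    5.25153
inbreeding_slope(run_scenario(scenario_spec(1, "M", 1, n_replicates = 40),
                              seed = 1), from = 7)
#> [1] 1.871243  (attributes: per-replicate slopes, se = 0.045)
```

Read: after 20 years of closed selection the average queen carries an
inbreeding coefficient of ~19.6%; mean colony performance has risen by
~4.7 initial phenotypic standard deviations; direct and maternal breeding
values have gained ~4.6 and ~5.2 initial genetic standard deviations.
Under mass selection with monoandry, inbreeding instead climbs by ~1.9
percentage points per year from year 7 onward. The analytic variance grid
behind the standardization is available directly:

```r
variance_table(setup_ids = 1, n_drones = c(1, 8))
#>   setup n_drones var_dir var_mat corr_dir_mat sigma2_P h2_dir h2_mat
#> 1     1        1      10      10            0    47.50   0.21   0.21
#> 2     1        8      10      10            0    43.13   0.23   0.23
```

`run_replicate()` gives the per-year trajectory of a single replicate;
`write_scenario_outputs()` dumps per-scenario trajectory CSVs, an endpoint
CSV and a JSON manifest. The methods vignette
(`vignettes/honeybee-breeding-scheme.Rmd`) documents the model,
the kinship algebra, the year indexing and all design choices.

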