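# tdrp

Viral evolutionary rate estimates are not constant in time: the shorter the
timescale over which a rate is measured, the faster the virus appears to
evolve. This time-dependent rate phenomenon (TDRP) spans published rate
catalogs from days to hundreds of millions of years and confounds any
analysis that transfers a rate estimate across timescales — most famously
the dating of lentivirus origins, where standard clocks give tens of
thousands of years while paleovirology demands millions.

`tdrp` is an R package for analysing and correcting this phenomenon. It is
aimed at molecular evolutionists who work with rate catalogs (one published
substitution-rate estimate per row, with taxonomy and phylogenetic
annotations) and with posterior samples of substitution-unit phylogenies.

## The model

All analyses rest on the empirical power-law rate-decay curve

    log10(r̄) = α + β · log10(t)        (equivalently  r̄ = 10^α · t^β)

where `r̄` is an average rate estimate in substitutions/site/year (s/n/y),
`t` the timescale of measurement in years, `α` the implied 1-year rate
(log10), and `β < 0` the decay slope. The package provides:

* **Catalog handling and resampling** — a validated catalog container with
  CSV I/O; constrained resampling into pseudoreplicated subsets that keep
  at most one rate per virus and one alternative grouping per
  phylogenetic-independence block, while retaining at least one short-term
  (< 1,000 y) and one long-term rate per Baltimore group.
* **Rate-decay regression** — three nested OLS forms on the log-log scale
  (one line; common slope with per-group intercepts; separate slopes),
  extra-sum-of-squares F comparisons, single-step max-|t| pairwise
  intercept contrasts, parameter-set draws pooled across replicates,
  Fisher-combined p-values, and shortest-interval HPD summaries.
* **Sensitivity simulation** — a nonhomogeneous Poisson generator with
  instantaneous rate `r_t = r0 · t^(−β)` (expected count
  `L·r0·T^(1−β)/(1−β)`), shuffling of short-term substitution counts to
  emulate rate estimates with no temporal signal, and paired Wilcoxon /
  Bonferroni comparisons against the unshuffled control.
* **TDRP-calibrated dating** — conversion of substitution-unit node heights
  `s` to calendar ages via `t = (s/10^α)^(1/(β+1))`, with `α` solved per
  posterior tree from a single calibrated node
  (`α = log10(s_cal) − (β+1)·log10(t_cal)`) and `β` drawn from the
  regression's slope sample; per-clade posterior age summaries with 95%
  HPDs.
* **A synthetic-data module** — generators for rate catalogs with known
  group intercepts/shared slope and nested independence blocks, and for
  posterior tree samples with known node ages, used throughout the tests.

## Worked example

```r
library(tdrp)

## a catalog shaped like the published 396-estimate census
catalog <- generate_synthetic_catalog(table1_config(seed = 1))
catalog
#> rate_dataset 'synthetic catalog (seed 1)': 396 rate estimates, 215 viruses, 78 blocks
#>       long short
#>   I     12     9
#>   II     2    45
#>   IV     1   122
#>   V      3   103
#>   VI    16    69
#>   VII    3    11

## pooled rate-decay analysis over pseudoreplicated subsets
res <- run_replicate_analysis(catalog, n_replicates = 100, seed = 2)
res
#> pooled rate-decay analysis: 100/100 replicates (100 draws each)
#>   coefficient median hpd_lower hpd_upper
#> 1           I -3.379    -3.773    -2.999
#> 2          II -2.773    -3.031    -2.520
#> 3          IV -2.084    -2.265    -1.903
#> 4           V -2.273    -2.457    -2.084
#> 5          VI -2.990    -3.201    -2.774
#> 6         VII -3.097    -3.562    -2.624
#> 7           x -0.639    -0.690    -0.589
#> median R^2 = 0.945
#>   p_slope_common combined p < 0.001 (p < 0.05 in 100/100)
#>   p_slope_adj    combined p < 0.001 (p < 0.05 in 100/100)
#>   p_group        combined p < 0.001 (p < 0.05 in 100/100)
#>   p_slope_het    combined p = 0.00112 (p < 0.05 in 8/100)
```

The shared decay slope (`x`) is recovered at −0.64 (95% HPD −0.69, −0.59)
against a generating value of −0.65, and each group's intercept (its
implied 1-year rate, log10 s/n/y) sits within the pooled HPD of its
generating value: dsDNA viruses slowest (`I` ≈ 10^−3.4 s/n/y), (+)ssRNA
viruses fastest (`IV` ≈ 10^−2.1 s/n/y). The time term and the group effect
are supported in every replicate, while per-group slopes add nothing
(8/100 replicates nominally significant).

The same machinery drives the sensitivity experiment:

```r
sens <- run_sensitivity(sensitivity_config(n_sims = 100, seed = 3))
round(sens$summary[, 1:5], 4)
#>   fraction median_slope slope_hpd_lower slope_hpd_upper median_intercept
#> 1      0.0      -0.6462         -0.7220         -0.5677           0.0071
#> 2      0.2      -0.6573         -0.7288         -0.5853           0.0048
#> 3      0.4      -0.6756         -0.7359         -0.6020           0.0072
#> 4      0.6      -0.6943         -0.7636         -0.6270           0.0073
#> 5      0.8      -0.7078         -0.7693         -0.6400           0.0101
#> 6      1.0      -0.7159         -0.8139         -0.6585           0.0079
```

Fitted slopes drift only from −0.65 to −0.72 even when **all** 50
short-term counts are shuffled, and the intercepts stay near
7 × 10⁻³ s/n/y: the overall rate-decay inference is robust to short-term
estimates that carry no temporal signal. (Restricting the same experiment
to short-term entries — `mode = "short_only"` — instead drives the slope to
−1, the signature of count/timescale independence.)

A shell entry point wrapping the same functions ships in
`inst/scripts/tdrp`:

```sh
tdrp generate --preset table1 --seed 7 --out run1
tdrp fit --catalog run1/catalog.csv --level group --replicates 1000 --seed 7 --out run1/fit
tdrp sensitivity --mode short_only --sims 100 --seed 7 --out run1/sens
tdrp date --trees post.nwk --calib calib.yaml --seed 7 --out run1/dates
```

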