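---
title: "Methods: power-law rate decay, pseudoreplication, and TDRP-calibrated dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power-law rate decay, pseudoreplication, and TDRP-calibrated dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrp)
```

## The model and its assumptions

Every analysis in `tdrp` rests on one empirical relationship between an
average substitution-rate estimate $\bar r$ (substitutions/site/year,
s/n/y) and the timescale $t$ (years) over which it was measured:

$$\log_{10}\bar r = \alpha + \beta\,\log_{10} t
  \qquad\Longleftrightarrow\qquad \bar r = 10^{\alpha}\,t^{\beta},$$

with $\beta < 0$: rate estimates decay as a power law in their measurement
timescale. $\alpha$ is the implied 1-year rate on the log10 scale, so
$10^{\alpha}$ is directly comparable to short-term rates from
heterochronous sequence data. The model is *descriptive*: it says nothing
about why rates decay (purifying selection on transient deleterious
mutations, site saturation, and estimation artefacts are all candidates),
only that the decay is log-log linear. On data spanning eight orders of
magnitude in $t$ this one assumption does the heavy lifting; all inference
is ordinary least squares on the transformed scale, and residual scatter is
treated as i.i.d. normal in $\log_{10}\bar r$.

Three nested fixed-effects forms are fitted (`fit_loglog()`):

1. `common_line` — one $(\alpha, \beta)$ for all records;
2. `common_slope` — one $\alpha_g$ per category (Baltimore group or genus),
   one shared $\beta$;
3. `group_slopes` — separate $(\alpha_g, \beta_g)$ per category.

Comparing 1 vs 2 (extra-sum-of-squares F, `compare_forms()`) asks whether
categories differ in level once decay is accounted for; 2 vs 3 asks whether
the decay *speed* itself differs. The categorical designs drop the
reference level (`~ 0 + g + x`), so every reported intercept is an
interpretable per-category $\alpha_g$; $R^2$ is always computed about the
grand mean so it is comparable across forms. A category list that collapses
to a single level degenerates gracefully to the common line, with the
intercept renamed.

## Phylogenetic pseudoreplication

Published rate estimates are not independent draws: one virus contributes
several estimates, and estimates for nested taxa (e.g. two alphaherpesvirus
species inside the alphaherpesvirus clade inside the alpha+beta clade)
share phylogenetic history. The catalog schema encodes this with
*independence blocks*: each block lists one or more mutually exclusive
*alternatives*, each alternative a set of viruses. `sample_pseudoreplicate()`
draws, uniformly, one alternative per block and then one record per virus,
and accepts the subset only if every Baltimore group keeps at least one
short-term (< 1,000 y) and one long-term record — the condition under which
a per-group decay line is estimable. Enforcement is by rejection sampling
(up to 10,000 attempts) applied to the *final* subset; rejection preserves
the uniform-choice semantics exactly, which matters for the chi-square
uniformity property test. The constraint check happens after per-virus
record selection because the constraint is about the subset actually
analysed, not about intermediate states.

The 1,000-subset default mirrors the analysis the package reimplements.
Per-subset p-values for (a) the time term, (b) the group effect and (c)
slope heterogeneity are combined with Fisher's method. Two caveats are
deliberate and documented rather than corrected:

* Fisher's method assumes independent p-values; pseudoreplicates share
  records, so the combined p is anti-conservative. It is reported verbatim
  (the procedure being reimplemented does the same), alongside the more
  robust count of replicates significant at 0.05. On a synthetic catalog
  whose groups truly share one slope, the heterogeneity test is nominally
  significant in only ~5–10% of replicates while the Fisher-combined p can
  dip below 0.05 — read the counts, not only the combined value.
* Because the time-term p-value can be taken from form 1 or form 2 and the
  source analysis does not say which fed its per-replicate significance
  counts, both (`p_slope_common`, `p_slope_adj`) are recorded.

Estimation uncertainty is pooled by drawing 100 parameter sets per
replicate from the multivariate normal with the OLS coefficient estimates
and covariance — the sampling distribution of the estimator, the natural
frequentist analogue of posterior draws — and concatenating them
(100,000 draws at the full 1,000-replicate scale). Summaries are medians
and 95% HPD intervals.

Pairwise intercept contrasts (`pairwise_intercepts()`) use the single-step
max-$|t|$ adjustment: the adjusted p of a contrast is the probability that
the largest absolute contrast statistic, under the joint t distribution
implied by the coefficient covariance, exceeds the observed one. The joint
tail is Monte-Carlo approximated (50,000 draws under a fixed internal seed,
so results are reproducible and adjusted p ≥ raw p by construction); a test
verifies agreement with `multcomp::glht` to ~0.002. Holm is available as a
fallback. Contrasts are taken on the common-slope form's intercepts: when
slope heterogeneity is non-significant, form 2's $\alpha_g$ are the
comparable "rate at one year" quantities.

## The synthetic catalog generator

`generate_synthetic_catalog()` draws records from exactly the structure the
regression assumes: per-group intercepts, a shared slope, normal scatter in
log10 units, log-uniform timescales, virus multiplicity of 1–3 records, and
term-pure independence blocks with `nesting_depth` alternatives of 1–2
viruses. `table1_config()` fixes the census at the published catalog's
counts (21/47/123/106/85/14 records in groups I/II/IV/V/VI/VII; 359 short +
37 long), the fitted group intercepts, slope −0.65, and scatter
`noise_sd = 0.4` log10 units — chosen once so that the common-slope fit's
$R^2$ lands near 0.9, the regime the method operates in on real catalogs.
Timescale ranges default to the observed short (0.16–760 y) and long
(6,600–2.28 × 10⁸ y) ranges, reproducing the empirical gap around the
1,000-year cutoff (which is why the boundary convention — exactly 1,000 y
counts as long — never matters in practice).

What the generator does *not* emulate: heteroscedastic measurement error
(real long-term rates are calibration-limited, not scatter-limited),
correlation between a virus's multiple estimates, genus structure beyond a
one-genus-per-group label, and any deviation from log-log linearity. A
passing recovery test therefore shows the estimator is consistent for the
model it assumes — not that real catalogs satisfy that model.

## Short-term analyses

`run_short_term_analysis()` filters to records with $t < 1000$ y and drops
any Baltimore group whose *capacity* — the largest number of
phylogenetically independent short-term records a single subset can contain
(one per virus, best alternative per block) — is strictly below 10. The
capacity criterion reproduces the "strictly fewer than 10 independent
short-term rates in each data subset" exclusion without needing the
replicates themselves, because the per-subset count can only reach the
capacity bound. The remaining groups are resampled and fitted with the same
machinery, minus the long-term constraint.

## The sensitivity simulator

The simulator asks: how badly do *erroneous* short-term rates — estimates
from data with no temporal signal, where the substitution count is
independent of the timescale — bias the fitted decay curve? Substitutions
accumulate as a nonhomogeneous Poisson process with per-site intensity
$r_t = r_0 t^{-\beta}$, so a sequence of $L$ sites observed over $T$ years
accumulates $\mathbb E[k] = L\,r_0\,T^{1-\beta}/(1-\beta)$ substitutions
(exponents $\beta \ge 1$ are redrawn; the integral diverges). Defaults
follow the experiment being reproduced: 50 short entries (log-uniform
10–1,000 y) and 5 long (10³–10⁸ y), $L = 1000$,
$\beta \sim \mathcal N(0.65, 0.041)$, $r_0$ log-uniform on
$[10^{-4}, 10^{-2}]$ s/n/y, one $(\beta, r_0)$ pair per set, 100
simulations per shuffling fraction. Average rates are $k/(LT)$ — per-site,
so intercepts land on the s/n/y scale of the catalog analyses.

Two numerical details matter:

* **The zero-count rerun rule is not cosmetic.** A set containing any
  $k = 0$ is discarded and redrawn with fresh parameters. Small-$r_0$ sets
  are overwhelmingly likely to produce a zero count at the short end, so
  surviving sets skew toward larger $r_0$; this selection lifts the median
  control intercept from the naive $\mathrm{med}(r_0)/(1-\beta) \approx
  2.9\times10^{-3}$ toward the ~$7\times10^{-3}$ s/n/y actually observed.
  Dropping the rule (or Poisson-truncating instead) would change the
  intercept results materially.
* **Shuffling** replaces a round-half-up fraction of the 50 short-term
  counts by a uniform permutation among themselves, conserving the count
  multiset; a permutation may fix points, which is the correct uniform
  semantics.

Each fraction is compared with the control by a two-sided Wilcoxon
signed-rank test on replicate-index-paired slopes and intercepts
(Bonferroni over the five non-control fractions; zero differences dropped,
all-zero pairs give p = 1). By default every fraction simulates its own
100 sets, so the index pairing is nominal: this is the design under which
the published robustness pattern — no detectable intercept shift even at
100% erroneous short-term rates, slope shift undetectable at 20% — is
reproducible. Sharing one base simulation across fractions
(`shared_bases = TRUE`) makes the pairing informative and the test far more
powerful; it detects even the 20% setting, which is statistically
legitimate but answers a different question. The choice is a config switch
with the independent design as default.

In `short_only` mode both simulation and fitting are restricted to the 50
short-term entries; there the same shuffling drives the slope toward −1
(pure $\bar r = c/t$ behaviour) and inflates the intercept — erroneous
rates that are harmless to the overall curve wreck the short-term curve.

## TDRP-calibrated dating

Given an ultrametric phylogeny whose node heights $s$ are in
substitutions/site (a strict-clock analysis with the rate fixed to 1), the
decay model integrates to a substitutions-to-time map. Writing
$\log_{10}(s/t) = \alpha + \beta \log_{10} t$ and solving:

$$t = \left(\frac{s}{10^{\alpha}}\right)^{1/(\beta+1)},
  \qquad
  \alpha = \log_{10} s_{\mathrm{cal}} - (\beta+1)\log_{10} t_{\mathrm{cal}}.$$

The map is strictly increasing in $s$ iff $\beta > -1$, which the
`tdrp_clock` validity check enforces; node-age order therefore always
equals node-height order. `date_posterior()` applies the map per posterior
tree: extract $s_{\mathrm{cal}}$ at the MRCA of the two calibration taxa,
draw one $t_{\mathrm{cal}}$ from the calibration normal (truncated at zero
— irrelevant at the default mean 10,500 y, sd $500/1.96 = 255.10$ y, but
stated for safety), draw one $\beta$ from the regression's slope sample
(values $\le -1$ redrawn), solve $\alpha$, convert every internal node.
One $(t_{\mathrm{cal}}, \beta)$ pair per tree propagates calibration and
slope uncertainty into the age posteriors. Clades are matched across trees
by leaf-label set; a tree lacking a clade contributes no draw, and each
summary row carries the clade's posterior support. The calibration is
symmetric-normal even though a geographic separation date is a lower bound;
ages should accordingly be read as lower-bound estimates.

Ultrametricity is validated with a relative tolerance (root-to-tip spread
$\le 10^{-6}$ of tree height by default, configurable) rather than exactly,
because Newick round-trips truncate branch lengths.

`generate_synthetic_posterior()` inverts the pipeline for testing: true
ages $t$ map to heights $10^{\alpha} t^{\beta+1}$, multiplied by lognormal
jitter and re-monotonised (a parent is nudged just above its tallest child)
so every generated tree is a valid ultrametric phylogeny. With zero jitter,
dating must return the true ages to machine precision; with jitter, a
200-run study in the test suite checks that truths drawn from the
calibration prior fall inside the 95% HPDs at roughly the nominal rate.
Reproducing the published lentivirus node ages themselves requires the
integrase alignment and a Bayesian tree-inference run, which is out of
scope here; the synthetic-posterior recovery is the correctness surface.

## Numerical choices

* All logarithms are base 10, in both regression and dating.
* HPD intervals (`hpd_interval()`) are the shortest contiguous window of
  sorted draws containing $\lceil 0.95\,n\rceil$ of them; ties resolve to
  the leftmost window, so the function is deterministic.
* Fisher's method clamps p = 0 (underflow) to the smallest positive double
  before logging; combined p-values below 0.001 are floored *in display
  only* ("< 0.001"), with raw values retained in the objects.
* Parameter draws repair covariance matrices whose smallest eigenvalue is
  negative within $10^{-8}$ of the largest (clipping to zero) and refuse
  anything worse.
* Saturated fits (as many records as coefficients) are allowed — the
  two-point line is pedagogically useful — and return NaN standard errors.
* Selection counts for shuffling use round-half-up; every documented
  fraction of 50 gives an exact integer anyway.
* Replicate failures (singular designs) are caught, counted and skipped;
  pooling proceeds over successes.

## Problem sizes in the test suite

The suite runs everything at reduced but statistically meaningful scale,
chosen as the smallest sizes at which the distributional assertions have
comfortable Monte-Carlo margins: 40–100 pseudoreplicates (vs 1,000),
100 sensitivity simulations per setting (the original scale), 10,000 draws
for the uniformity chi-square, 1,000–2,000 simulations for type-I-error
checks, and 200 repetitions × 40 trees for the dating coverage study. The
acceptance script runs the sensitivity experiments at full scale.

## Known limitations

* Fixed-effects OLS only; no mixed-effects or phylogenetic-regression
  alternatives, and no joint estimation of the decay curve inside a tree
  model (the natural next step, which would also propagate $s$ uncertainty
  properly).
* The combined p-values inherit the dependence problem described above.
* Dating extrapolates a curve fitted mostly at $t \le 10^8$ y from a single
  calibration node; uncertainty grows rapidly with depth and the reported
  HPDs can span orders of magnitude — that is the method, not a bug.
* Independence blocks are user-supplied annotations; the package does not
  infer them from trees.
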