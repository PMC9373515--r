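---
title: "Scoring breakfast diet quality from 24-hour recalls with NRF9.3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring breakfast diet quality from 24-hour recalls with NRF9.3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrfbk)
```

## The problem

National dietary surveys record what people eat through interviewer-led
24-hour recalls: one row per food line, tagged with a meal code (1 =
breakfast), a food code resolvable in a food composition table, and grams
as consumed. This package turns such meal-coded recall data into an
analysis of *breakfast* diet quality: who skips breakfast, how
nutrient-dense the breakfasts of consumers are, which food groups those
breakfasts are built from, and how much of the day's nutrient
recommendations breakfast actually supplies.

The core measure is the Nutrient-Rich Food index NRF9.3, a nutrient
profiling score over nine qualifying nutrients (protein, fiber, vitamins
A, C and D, calcium, iron, potassium, magnesium) and three limiting ones
(total sugar -- standing in for added sugar, which 24-h recalls rarely
resolve -- saturated fat, and sodium).

## The model

For an intake window with nutrient vector $x$ and energy $E$ (kcal), every
amount is first expressed per 2000 kcal of the window itself:
$\tilde{x}_i = x_i \cdot 2000 / E$. Then

$$\mathrm{NR} = \sum_{i=1}^{9} \min\!\left(1, \frac{\tilde{x}_i}{\mathrm{DV}_i}\right),
\qquad
\mathrm{LIM} = \sum_{j=1}^{3} \max\!\left(0, \frac{\tilde{x}_j}{\mathrm{MRV}_j} - 1\right),
\qquad
\mathrm{NRF9.3} = (\mathrm{NR} - \mathrm{LIM}) \times 100 .$$

Three conventions matter and are worth stating explicitly:

* **Capping.** Each qualifying fraction is capped at 1, so an extreme
  intake of one nutrient cannot compensate a deficiency in another. An
  uncapped variant is available (`cap_nr = FALSE`) for sensitivity
  analysis.
* **Excess only, per nutrient.** Each limiting fraction contributes only
  its excess over 1, floored at zero *per nutrient*. Applying a single
  "-1" after the sum would let a nutrient below its ceiling offset
  another above it, which contradicts the intent of penalising only
  over-consumption; the per-nutrient floor is therefore the implemented
  reading. No upper cap is applied to LIM.
* **Energy normalisation.** Because $\tilde{x}$ divides by the window's
  own energy, the score is invariant under scaling the whole window by
  any $c > 0$. The maximum attainable score is 900, reached exactly when
  all nine capped fractions equal 1 and LIM is 0.

Default reference amounts (Philippine Dietary Reference Intake based) are
protein 50 g, fiber 25 g, vitamin A 1500 RE, vitamin C 60 mg, vitamin D
10 µg, calcium 1000 mg, iron 18 mg, potassium 3500 mg, magnesium 400 mg;
ceilings: total sugar 50 g, saturated fat 20 g, sodium 2400 mg. Stratum
specific tables (age group × sex) can be supplied through
`read_reference_yaml()` without touching the scoring code.

## Windows, skippers, tertiles

Surveys of this design collect day 1 for everyone and a second,
non-consecutive day for about half the sample. All windows in this package
are therefore *per-day averages over the days an individual has on
record*, which puts one-day and two-day individuals on the same scale. A
recorded day without breakfast lines contributes 0 kcal -- a skipped
breakfast is data, not missingness.

An individual is a **breakfast skipper** when the breakfast window
supplies less than 50 kcal (including no breakfast at all), a consumer at
or above 50 kcal. Whether the rule should see only day 1 or the two-day
mean is not determined by the rule itself; the package defaults to the
two-day mean, consistent with the habitual-intake framing of the rest of
the pipeline, and exposes `day1_only = TRUE` for the stricter single-day
reading. Skippers are excluded from breakfast scoring (there is no
breakfast to score); a zero-energy window passed to `nrf93()` is a hard
error rather than a zero score.

Scored individuals are split into within-age-group **tertiles** of the
NRF9.3 score by ranking (ascending, ties broken by id) and cutting the
ranks at $\lceil n/3 \rceil$ and $\lceil 2n/3 \rceil$. Rank-based
splitting with a deterministic tie-break was chosen over quantile
interpolation deliberately: quantile conventions differ across software,
whereas the rank split is reproducible everywhere and guarantees tertile
sizes differing by at most one. Ranks are unweighted by default (the
tertile is a property of the sample, not the expanded population).

## Food groups, contributions, outliers

A person is a *consumer* of a food group at breakfast when their per-day
average intake of that group is at least 10 g. Group tables report the
weighted mean intake **among consumers** paired with the weighted percent
of consumers -- a mean over everyone would conflate portion size with
popularity. Association between consuming a group and the score tertile
is tested by the rank-biserial correlation of the tertile rank against
the 0/1 consumer score, computed through its Mann-Whitney equivalent
(`wilcox.test` with tie-corrected normal approximation). The construction
of this test for a 3-level ordered factor is one defensible reading, not
the only one; it is reported as such.

Contribution reports express breakfast both as a percent of the same
population's daily intake and as a percent of the daily recommendation,
flagging nutrients below the 20% benchmark (a breakfast should supply
roughly 20-25% of the day). Population-level percentages are ratios of
weighted mean intakes by default -- robust to near-zero individual
denominators -- with a per-individual-ratio mode available, since the
choice genuinely affects skewed nutrients. Both windows use the same
restricted population (e.g. the healthiest tertile), which guarantees the
breakfast contribution can never exceed the daily one.

Implausible intakes are handled by substitution, not exclusion: within a
sex × age-group stratum, values above $1.5 \times P_{99}$ are replaced by
a uniform draw from $[P_{95},\, 1.5 \times P_{99}]$, with both
percentiles computed from the original values in a single pass (the
procedure is one substitution step, not an iteration, and is idempotent
on its own output). Percentiles use linear interpolation between order
statistics (`quantile` type 7), recorded here because the convention is
not otherwise pinned down. Energy is never cleaned by this rule; strata
under 20 individuals are skipped with a warning rather than cleaned on
unstable percentiles.

## Usual intake: a variance-shrinkage stand-in

Single recall days mix true between-person differences with day-to-day
noise. With a repeat day on part of the sample, the within-person
variance is estimable on a transformed scale (log1p by default; intakes
are skewed and may be zero) as
$\hat\sigma^2_w = \mathrm{mean}\big((x_{i1}-x_{i2})^2/2\big)$ over
two-day individuals, and the between-person variance as
$\hat\sigma^2_b = \max\big(0,\ \mathrm{var}(\bar x_i) - \hat\sigma^2_w\,
\mathrm{mean}(1/k_i)\big)$. Person means are then shrunk toward the grand
mean by the best-linear-predictor factor
$\sigma^2_b / (\sigma^2_b + \sigma^2_w / k_i)$ and back-transformed.

This is an explicitly simplified stand-in for full measurement-error
deconvolution software: it reproduces the defining behaviour of
usual-intake correction -- the distribution of usual intakes is strictly
narrower than the distribution of single-day intakes whenever both
variance components are positive -- but it does not estimate percentiles
of the deconvolved usual-intake distribution and makes no covariate
adjustment. Means produced this way are not claimed to match estimates
from deconvolution software numerically. The pipeline estimates the
components within each age group, since portion scale differs by age.

## Weighted estimation and tests

Sampling weights are expansion factors. All descriptive estimates
normalise them to mean one and report the weighted mean with
$\mathrm{SE} = \sqrt{\sum \tilde w_i^2 (x_i - \bar x_w)^2} \big/ \sum
\tilde w_i$; with equal weights everything reduces exactly to the
unweighted estimate. No design-based (cluster/stratum) variance
correction is applied anywhere -- these are simple weighted estimates.

Two tests are provided. The **trend test** regresses a nutrient on the
tertile index 1/2/3 by weighted least squares; because expansion weights
are not precision weights, the slope's p-value uses the HC1 sandwich
variance rather than classical WLS inference (which treats high-weight
observations as low-variance and over-rejects under the null: simulated
null rejection 0.085 classical vs 0.056 HC1 at gamma weights, n = 90).
The **association test** for regularity tables is a Pearson chi-square on
the weighted contingency table rescaled to the unweighted sample size.
That rescaling is exactly calibrated under homogeneous weights; under
variable weights it ignores the design effect and is anti-conservative,
which is the accepted price of the naive approach and the reason the
null-calibration checks run it with unit weights.

## The synthetic-data generator

`simulate_survey()` emulates the *structure* of such a survey with known
ground truth: four age groups; a second recall day for a Bernoulli(0.5)
subset; meal-coded lines for breakfast, lunch, supper and two snacks; a
built-in 13-food menu spanning 13 food groups typical of Philippine
meals (rice, coffee, sugars, cooking oil, egg, fish, meat, two vegetable
groups, bread, powdered milk, cacao beverages, fruit).

Portions follow a log-normal model:
$\mathrm{grams} = \exp(\mu_g + a_{g(i)} + b_i + w_{id} + \varepsilon)$,
with a person effect $b_i \sim N(0, \sigma_b^2)$ shared across days, a
day effect $w_{id} \sim N(0, \sigma_w^2)$ shared across a day's lines,
per-line portion noise with SD 0.1, and an age-group shift $a_g$
(children eat smaller portions). Defaults $\sigma_b = 0.4$, $\sigma_w =
0.3$ are realistic magnitudes for log-scale intake variation; skipper
probability defaults to 0.02 in children/adolescents and 0.04 in
adults/elderly, the magnitudes reported for Philippine survey data.

Two design choices depart from the most naive generator and exist so the
generator honours its own contract that the variance components of log
breakfast energy are recoverable:

* **Habitual menus.** Which foods a person eats at a meal is drawn once
  per person and reused on both days. Redrawing the plate every day would
  add large composition noise to the within-person variance, making the
  nominal $\sigma_w$ unrecoverable from data -- and habitual, repetitive
  breakfasts are the empirically accurate description anyway.
* **A universal staple.** Rice appears in every breakfast with
  probability one, with optional companions of modest energy, so
  between-person composition heterogeneity stays small relative to
  $\sigma_b$. In recovery runs at $n = 2000$ per age group the estimated
  SDs land within about 15% of the nominal values, inside the ±20%
  tolerance used by the checks.

Skippers are simulated by *thinning*: their breakfast lines are scaled
down to a random 5-30 kcal per recorded day, so the under-50-kcal rule is
exercised on real records rather than on missing meals. Conversely, the
rare non-skipper whose drawn breakfast falls under 50 kcal is scaled up
to 55-85 kcal, so the simulated skipper flag is the sole ground truth of
skipper status. Sampling weights are drawn from a shifted gamma
distribution rescaled to mean one -- enough to exercise weighted
estimators without claiming to reproduce any real survey design.

What the generator does **not** emulate: multistage cluster sampling and
its design effects, real Philippine intake distributions or consumer
percentages, correlations between diet quality and covariates (covariates
are drawn independently), seasonal or weekday effects, and within-person
correlation between nutrients beyond what shared foods induce. Passing
tests on synthetic data therefore demonstrate the correctness of the
computations and the recoverability of known parameters -- not numerical
agreement with any published survey estimate, which would require the
non-public microdata.

## Numerical choices and degenerate inputs

* Tertiles: rank split, stable ties by id; `n < 3` is an error.
* Percentiles: `quantile` type 7 throughout.
* `nrf93()` on zero or negative energy: error (callers exclude skippers).
* Chi-square on a degenerate margin (all consumers): p reported as `NA`.
* Trend test with constant values: slope 0, direction `"none"`.
* Variance decomposition with no two-day individuals: error; under 30 of
  them: warning.
* `max(0, ...)` floors protect both LIM fractions and $\hat\sigma^2_b$.
* Empty strata are excluded from regularity tables with a warning; an
  empty restricted population in contribution reports is an error.

## Problem sizes used by the checks

The package's property checks run the generator at 40-500 individuals;
the parameter-recovery check uses 2000 per age group (the size at which
±20% recovery of the variance components is a comfortable bound), and
null calibration of the two tests uses 500 replicates at n = 90 and
n = 300. These sizes were chosen so each property is tested at the scale
where its statistical guarantee is meaningful.

## Limitations

The usual-intake module is a best-linear-predictor stand-in, not a
deconvolution; weighted variances ignore design effects; the ANCOVA-style
covariate-adjusted group comparisons found in survey reports are out of
scope (the report schema leaves room for externally computed p-values);
and supplement intake, retention factors and proprietary food-composition
databases are not modelled. The built-in composition table is synthetic:
plausible magnitudes for testing, not reference data for nutrition work.
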