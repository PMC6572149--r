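---
title: "Probabilistic risk assessment of miners' unsafe behaviors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic risk assessment of miners' unsafe behaviors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubrisk)
```

## The model

Gas explosions are the dominant severe-accident type in underground coal
mining, and the ignition side of the fire triangle is almost always tied to
human activity. `ubrisk` quantifies that link at the level of *working
types* — occupational roles such as ventilation, gas prevention and fire
extinguishing, blasting, and electrician — and the 13 unsafe-behavior
classes of the Chinese accident-classification standard GB 6441-86.

The chain from coded accident records to risk is:

1. **Occurrence.** A table of accident citations, one `(working type,
   behavior class)` pair per accident, is tabulated into raw occurrence
   probabilities $P' = \text{count} / n_\text{accidents}$
   (`tabulate_occurrences()`, `occurrence_probability()`).

2. **Correction.** Raw frequencies from accident archives underestimate how
   often unsafe behavior actually occurs, and the deficit depends on
   context. Eight influencing factors — organizational ($a$ rules and
   regulations, $b$ education and training, $c$ safety reward),
   human-machine ($d$ workload, $e$ device, $f$ working environment) and
   personal ($g$ safety physiology/psychology, $h$ skills and knowledge) —
   are scored 0–10 (larger is worse) and combined into the correction
   factor
   $$F(x) = 1.5 - 0.0167\left[(0.2a + 0.6b + 0.2c) + \tfrac{d+e+f}{3} +
   \tfrac{g+h}{2}\right],$$
   with the revised probability $P = P' \cdot F(x)$. With the default
   coefficients $F \in [0.999, 1.5]$ and $F$ is strictly decreasing in
   every factor. Factor scores are elicited as triangular distributions
   per working type (`factor_profile()`, `sample_factors()`).

3. **Hazard.** The accident hazard index $I = B \cdot C$ multiplies a
   possibility grade $B \in \{1, 0.5, 0.1, 0.05, 0.01\}$ by a severity
   grade $C \in \{1,\dots,5\}$. Per cell, the elicited index is modelled
   as a normal distribution (`hazard_spec()`, `sample_hazard_index()`).

4. **Risk.** The behavior risk is $R = P \cdot I$, propagated by seeded
   Monte Carlo simulation (`simulate_behavior_risk()`,
   `simulate_working_type()`), summarized as sample mean, SD, quantiles
   and best-fitting family (`summarize_risk()`, `fit_distribution()`),
   and aggregated into per-working-type totals (`total_risk()`).

5. **Sensitivity.** Contribution-to-variance percentages attribute output
   variance to the stochastic inputs via signed normalized squared
   Spearman rank correlations (`contribution_to_variance()`,
   `sensitivity_pooled()`).

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `org_weights` | 0.2, 0.6, 0.2 | weights of $a, b, c$ inside the organizational group |
| `slope` | 0.0167 | sensitivity of $F$ to the grouped factor score |
| `intercept` | 1.5 | $F$ at all-zero (best) factor scores |
| `iterations` | 10,000 | Monte Carlo iterations per working type |
| `confidence` | 0.95 | level of the reported percentile interval |
| `truncation` | `"none"` | hazard positivity policy (`"resample"`, `"clip"` available) |
| `total_mode` | `"comonotonic"` | coupling of per-behavior hazard draws in totals |

Factor scores are dimensionless; triangular modes default to the range
midpoint (symmetric triangular), which makes each factor's mean equal its
midpoint. The elicitation convention uses the bands $[0,1]$ (good),
$[1,3]$ (moderate) and $[3,10]$ (poor), but any `0 <= lower <= mode <=
upper <= 10` is accepted.

The model coefficients themselves (0.0167, 1.5, the organizational
weights, and the grouping of $d$–$f$ and $g$–$h$ as unweighted means) are
taken from prior human-factor work and are configurable but not
re-estimated here.

## The built-in case study

`study_fixture()` packages a complete 200-accident gas-explosion study:
citation counts for 23 populated cells across the four key working types
(type totals 82/59/37/22, shares 41%/29.5%/18.5%/11%), triangular factor
ranges per working type, and a normal hazard spec per cell. At the
triangular means the correction factors evaluate to 1.376 (ventilation),
1.391 (gas prevention and fire extinguishing), 1.378 (blasting) and 1.376
(electrician).

Two source-table irregularities are handled explicitly:

* The blasting correction factor is printed as 1.78 in the source
  tabulation, but its own revised-probability column (e.g.
  $0.045 \to 0.06$) requires $\approx 1.378$, the formula value. The
  package uses the formula value throughout.
* The hazard SD of the gas-prevention / use-of-unsafe-devices cell is
  garbled in the source ("0.2 ± 0.0.135"). The fixture defaults to 0.135;
  the alternative reading 0.0135 (which better matches the printed risk
  SD of that cell) is available via `study_fixture(gas_uud_sd = 0.0135)`.

```{r fixture}
fx <- study_fixture()
head(occurrence_report(fx$study), 5)
```

## Numerical and design choices

**Unrounded probabilities.** Revised probabilities are carried at full
precision internally; the conventional 2-decimal rendering appears only in
report tables. Published risk tables for this study were evidently
computed from the *rounded* probabilities, so small cells (e.g. blasting
VDP, where $P$ = 0.0138 prints as 0.01) can differ from print by tens of
percent while large cells agree within a few percent. The engine does not
reproduce that rounding artifact.

**Shared factor draws.** Within one iteration, a working type's factor
draws (and hence $F$) are shared across its behavior classes: the factors
describe one population context per scenario, not per-behavior noise.

**Comonotonic totals.** Per-behavior hazard draws share a single uniform
stream per iteration by default, so the total's SD approximately equals
the sum of the component SDs — the convention the study's published totals
follow (ventilation: $0.264 + 0.006 + 0.060 + 0.006 + 0.013 \approx
0.349$). Independent coupling, the statistically conventional choice
(total variance = sum of variances), is available via
`total_mode = "independent"` and always yields a total SD no larger than
the comonotonic one. The published electrician total SD
($5.74 \times 10^{-1}$) exceeds the sum of its own component SDs tenfold
and is treated as a decimal-shift misprint; the engine reports
$\approx 5.7 \times 10^{-2}$.

**Hazard truncation.** The default `"none"` keeps raw normal draws,
because untruncated moment propagation reproduces the published SDs; a
small fraction of draws can then be negative for high-CV cells.
`"resample"` gives exact lower truncation at zero via the conditional
inverse CDF (preserving seed determinism and comonotonicity) and biases
means upward; `"clip"` floors draws at zero.

**Distribution fitting.** Candidates (normal, lognormal, triangular,
uniform) are moment-matched to the sample mean and SD and ranked by the
Kolmogorov–Smirnov statistic. Positive-support families are skipped, with
a note, when samples contain non-positive values — which under the default
truncation policy happens for exactly the high-CV cells the source labels
lognormal. This is a known tension: with a normal hazard index and a
nearly constant $P$ (the CV of $F$ is only about 1%), the product
$R = P \cdot I$ is itself close to normal, so the package does not assert
the lognormal label; it reports whatever family wins the KS comparison.

**Pooled sensitivity.** The default decomposition target is the pooled
per-iteration total risk over the four key working types, with one shared
uniform stream per factor (mapped through each type's own triangular
quantile) and one shared hazard stream. Plain rank correlation of the
factors with the stochastic total is, however, numerically hopeless here:
the hazard index contributes about 99.98% of the total variance, leaving
factor correlations of order $10^{-3}$ that drown in estimator noise at
any feasible sample size. The default estimator
(`method = "hazard-averaged"`) therefore correlates the factor streams
with the conditional mean total given the factors — obtained analytically
by integrating the comonotonic hazard sum, $\sum_b p_b I_b(u) = A + B\,
\Phi^{-1}(u)$, over $u$ — while the hazard stream is correlated with the
full stochastic total, and all nine squared correlations are normalized
jointly. This Rao–Blackwellization changes no sign and no ranking of the
true correlations; it only removes estimator noise. The spec-literal
estimator is available as `method = "plain"`. Because the factor signals
are weak, the decomposition defaults to $10^6$ iterations, in contrast to
the $10^4$ used for risk summaries.

Under the default estimator the decomposition is structurally stable
across seeds: the hazard index carries the largest, positive contribution;
all eight factors are negative (F decreases in each); and the working
environment ($f$) and workload ($d$) factors lead among the factors,
with the safety-psychology factor ($g$) a close third — the gap between
$d$ and $g$ is real but small (about 1% of their common magnitude), which
is why the high iteration default matters. Published percentage
magnitudes for this figure are not reproducible — the decomposed output
variable is not identifiable from the source — so only the sign and rank
structure is asserted.

## What the synthetic generator does and does not emulate

`generate_accident_records()` reproduces the count algebra of the study:
one working type and one behavior class per accident, so exact-mode
tabulation inverts generation, and multinomial mode draws cell counts from
the target frequencies. It does not synthesize narratives, dates,
severities or multi-citation accidents (the data model accepts
multi-citation records; the generator does not produce them). Passing
tests on synthetic tables therefore validates the tabulation-to-risk
pipeline, not the manual classification of real accident reports into
behavior codes.

## Problem sizes

Risk summaries use 10,000 iterations per working type — the study's own
simulation setting, at which per-cell mean estimates carry a Monte Carlo
SE of well under 1% of their value. The pooled sensitivity decomposition
uses $10^6$ iterations for the reasons above. The test suite and the
acceptance script both run at these sizes.

## Limitations

* Expert-elicited inputs (factor ranges, hazard means and SDs) are taken
  as given; no elicitation protocol is modelled.
* The correction model is linear with fixed group weights; interactions
  between factors are not represented.
* The hazard index conflates possibility and severity into one scalar;
  economic losses beyond the ordinal severity score are out of scope.
* Contribution-to-variance is a correlation measure, not a variance
  decomposition in the Sobol sense; with strongly dominant inputs the
  normalized percentages of minor inputs are scale-dependent.
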