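---
title: "morbsim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morbsim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`morbsim` is a discrete-time dynamic microsimulation of multi-morbidity in a
closed population aged 35 and over. Every individual carries fixed
attributes (sex, education, socio-economic status, residence), a
deterministic age, and a set of stochastic characteristics: marital status,
smoking, physical inactivity, BMI category, nine chronic diseases
(arthritis, cancer, CHD, dementia, depression, diabetes, hypertension,
respiratory disease, stroke), hearing and vision impairment, and an MMSE
cognition score. Cognitive impairment no dementia (CIND) is derived, not
stored: MMSE 0–20 without dementia.

Each simulated month, in a fixed order, every alive individual

1. survives a Bernoulli draw at the monthly survival probability for their
   current age, sex and calendar year;
2. ages by one month;
3. updates each stochastic characteristic with one categorical draw from
   its monthly transition distribution, in registry order (behaviours and
   marital status, then diseases, then impairments). Within a month, later
   updates see the already-updated values of earlier characteristics, which
   is the point of the monthly clock: co-dependent characteristics evolve
   jointly rather than in 2-year blocks.

The update order is a modelling choice (transitions over a month are
near-commutative because monthly probabilities are small); it is fixed and
documented so runs are auditable, and can be probed by re-ordering the
registry.

### Transition models

Transition probabilities over a 2-year observation interval are estimated
from a two-wave panel by maximum likelihood, one model per characteristic:

* binary logistic regression (`stats::glm`) for binary characteristics —
  fitted on the at-risk subset for absorbing (ever-diagnosed) diseases;
* proportional-odds ordinal regression (`MASS::polr`) for BMI category and
  the MMSE band;
* generalised (multinomial) logit (`nnet::multinom`) for marital status and
  smoking.

Covariates are the wave-1 characteristics named in the registry (age, sex,
education, SES, behaviours, selected disease cross-effects) plus the
characteristic's own lagged state; dementia never appears as a predictor
because dementia status is assigned outside the simulation. A constant
outcome raises an explicit degenerate-fit error. Separation (detected by
non-convergence or coefficients beyond ±15 on the logit scale) triggers a
warning and a refit with a lightly ridge-penalised IRLS (fixed penalty
0.01, intercept unpenalised), recorded in the model metadata; the light
penalty keeps estimates finite while a no-event stratum still predicts an
essentially vanishing probability.

### Interval-to-monthly conversion

The fitted models give 2-year probabilities. Under a constant-hazard
assumption the monthly equivalent of an interval probability $p$ is

$$m = 1 - (1 - p)^{1/24},$$

so compounding $m$ over 24 months reproduces $p$ exactly — a property the
test suite asserts to $10^{-9}$. For multi-state characteristics each
destination's 2-year probability is converted independently and the
stay-probability takes the remainder; the competing-risk renormalisation
error this introduces is second order in the (small) monthly probabilities,
and the distribution is asserted to stay proper to $10^{-12}$. Mortality
uses the analogous annual-to-monthly form $(1-q)^{1/12}$.

Transition rates are assumed time-invariant over the projection: the same
fitted models apply in every simulated month. Only mortality carries a
calendar trend.

### Mortality and the lifetable

Mortality is exogenous: an annual death-probability schedule by single year
of age, sex and calendar year, converted to monthly survival. Individual
characteristics do not modify mortality. The packaged default is a
synthetic Gompertz schedule (level calibrated so that period life
expectancy at 65 in 2015 is about 18.6 years for men and 21.2 for women,
with a 1.2% annual mortality improvement); it stands in for an official
national projection, which is external data, and is therefore clearly
labelled synthetic.

Period lifetables use the standard single-year construction with deaths at
mid-interval ($a_x = 0.5$), a terminal age of 105 closed with $q = 1$:
$l_{x+1} = l_x(1-q_x)$, $L_x = l_x - d_x/2$, $e_x = \sum_{y\ge x} L_y /
l_x$. These conventions are stated so results reproduce bit for bit.

### Dementia allocation

Dementia is allocated probabilistically *after* the simulation, conditional
on age group, MMSE band and community/care-home residence, from an
allocation table. Each individual draws one uniform quantile $u$ per run
and is demented in a snapshot iff $u < p_{\text{cell}}$. Because cell
probabilities rise with age and fall with MMSE, onset along a worsening
trajectory is monotone — the persistent quantile supplies cross-year
consistency that independent draws would not (an `independent` mode is
available). The shipped table is synthetic (rising with age, low MMSE and
care-home residence); the table estimated from cognitive-ageing study
microdata is not public. Expected prevalence per cell equals the cell
probability, which the tests check against binomial error.

### Outputs

Snapshots of the alive population are taken each July. Reporting follows
projection-table conventions: prevalence to 1 decimal place, represented
head counts (sample count × scale factor, default 100) to the nearest 100,
percent change rounded half-away-from-zero to 1 decimal place — rounding
applied only at the reporting layer. Multi-morbidity is counted over two
condition sets (nine diseases only; diseases plus hearing, vision and
CIND) and categorised 0, 1, 2, 3, 4+, with 2+ as the derived multi-morbid
indicator. The mental ill-health overlap (dementia, depression or CIND) is
tabulated by morbidity-count category; by default mental-ill-health
conditions count toward the category total (a toggle reads "k other
conditions" instead, since either reading of the published wording is
defensible).

### Sullivan health expectancy and decomposition

Years lived in morbidity category $c$ from age 65 weight lifetable
person-years with the age-specific category prevalence $\pi_c(x)$:

$$\text{years}_c = \frac{1}{l_{65}} \sum_{x \ge 65} \pi_c(x)\, L_x ,$$

so category years sum to total life expectancy by construction.
$\pi_c(x)$ comes from post-allocation snapshots, estimated in 5-year age
bands by default because single-year cells are noisy at reduced sample
sizes (`band_width = 1` gives raw single-year estimates); ages above the
last populated band carry the last band forward.

The change in category years between two settings (e.g. 2015 and 2035) is
split into a mortality and a prevalence component by symmetric two-way
stepwise replacement: each component averages the two replacement orders,
making the split order-invariant and exactly additive
(mortality + prevalence = total change, asserted to $10^{-12}$; equal
surfaces give a prevalence component of exactly zero). The published
decomposition's exact algorithm is not reproducible from the description,
so additivity and these cancellation cases pin the semantics here.

## The synthetic population

Access-restricted survey microdata cannot ship with the package, so a
seeded generator emulates the broad structure of the England 2014
population aged 35+ (about 30.4 million people; a 1% sample is roughly
303,589 individuals, the full-scale reference). The default sample size is
30,000 — a further tenfold reduction chosen so the full multi-replicate
projection runs in minutes on one CPU.

The generator draws an age-band/sex structure with roughly a third of the
sample 65+, age-graded education, marital status, smoking, inactivity and
residence, and condition flags from logistic-in-age prevalence curves with
odds multipliers linking inactivity, obesity and current smoking to
disease. Curve levels are loosely calibrated to published English
magnitudes at older ages (e.g. arthritis and hypertension near 50% at 65+,
stroke near 7%, dementia allocated to a few percent); they are explicitly
*not* estimates and the package makes no claim to reproduce published
absolute prevalence — those depend on restricted microdata. What the
synthetic population does support is verification: every statistical
contract (prevalence vs configured curves, survivorship vs lifetable,
onset vs closed-form hazard, parameter recovery) is testable against known
ground truth.

Features of real data the generator does not emulate: survey design
weights, clustering and non-response; item missingness (the real pipeline
imputes); cross-characteristic correlation beyond the configured risk-factor
multipliers; and any cohort trend in behaviours. Passing tests therefore
demonstrate the *machinery* is correct, not that projections from the
synthetic defaults describe England.

The two-wave panel generator evolves a base population under a known
ground-truth bundle, by default month by month with cross-characteristic
covariates frozen at wave 1 (matching the engine's conversion semantics,
with the own state evolving); an `interval` mode draws the wave-2 state
directly from the 2-year distribution. Parameter-recovery tests use the
`interval` mode, where the generator matches the fitted family exactly —
the standard way to validate an estimator; monthly-mode consistency for
binary characteristics is covered separately by the exact round-trip
property. Recovery on a 50,000-individual panel achieves ≥90% coverage of
fitted 95% confidence intervals across all coefficients.

## Numerical and design choices

* **Seeding.** One master seed drives everything; replicate $r$ and each
  pipeline stage derive deterministic sub-seeds (all below $2^{31}$), so a
  replicate is reproducible in isolation and a manifest reproduces a run.
* **Update order within a month** — mortality, ageing, behaviours,
  diseases, impairments — is fixed; see above.
* **Absorbing set.** Diseases are ever-diagnosed and absorbing, except
  depression, which remits (a self-limiting condition whose prevalence can
  fall even as survival improves); impairments and behaviours are
  recoverable. Configurable per characteristic.
* **Snapshots** are taken mid-year (July) to approximate period
  prevalence; configurable.
* **No entry cohorts**: the population is closed, so the 65+ of a later
  year are the 45+ of an earlier one — matching a base population recruited
  from age 35 precisely to feed ageing-in cohorts.
* **No calibration**: simulated totals are not aligned to external
  population counts; validation is post hoc.
* **Degenerate inputs**: constant outcomes, missing covariates, schedule
  gaps, uncovered allocation cells and empty strata raise typed errors (or
  warnings with null rows, for empty reporting strata) rather than
  propagating NaN.

## Problem sizes

Default test and acceptance runs use: 30,000 individuals × 10 replicates ×
258 months for the sensitivity harness; 50,000 individuals for
survivorship, hazard and parameter-recovery checks; 2,000–8,000 for unit
tests. The full suite runs in well under 15 minutes on one CPU.

## Known limitations

* Transition rates are time-invariant; no scenario machinery is included.
* Mortality ignores individual risk factors, so the simulator cannot show
  mortality selection by morbidity; the decomposition's mortality component
  reflects only the external schedule.
* The multi-state monthly conversion is exact only for binary
  characteristics; for ordinal/multinomial characteristics the monthly
  chain can traverse intermediate states within an interval, a second-order
  effect accepted by design.
* Replicate-to-replicate ranges at the default 30,000-individual scale are
  governed by binomial noise of order
  $\sqrt{p(1-p)/n_{65+}} \approx 0.3{-}0.4$ percentage points; statements
  about sub-percentage-point stability that hold at full 1%-sample scale
  sit at the edge of this noise floor at the reduced size.
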