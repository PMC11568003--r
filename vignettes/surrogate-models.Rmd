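---
title: "Surrogate fracture-probability models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate fracture-probability models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrofrax)
```

## The problem

Fracture-risk tools report a 10-year probability of hip fracture and of major
osteoporotic fracture (MOF: hip, clinical spine, distal forearm, proximal
humerus). That probability depends on two country-specific inputs — the
age/sex-specific fracture hazard and the competing death hazard — and both
shape the answer: an 80-year-old facing high background mortality has a
*lower* absolute fracture probability than an otherwise identical subject in
a low-mortality country, simply because death is more likely to come first.
When a country lacks its own fracture incidence, a surrogate model borrows a
donor country's incidence and pairs it with the index country's mortality.
`surrofrax` implements that construction end to end and provides the
machinery to ask the two questions that matter about a surrogate: does it
preserve the *ranking* of subjects by risk, and how far do its absolute
probabilities shift?

## The competing-risk engine

All probabilities are cause-specific cumulative incidences with hazards
piecewise constant on one-year intervals. For year $i$ with fracture hazard
$f_i$ and death hazard $d_i$ (both per person-year),

$$P = \sum_{i=1}^{H} S_{i-1}\,\frac{f_i}{f_i+d_i}\,\bigl(1-e^{-(f_i+d_i)}\bigr),
\qquad S_i = \exp\Bigl(-\sum_{j\le i}(f_j+d_j)\Bigr),\ S_0=1 .$$

The factor $f_i/(f_i+d_i)$ is exact for two independent exponential clocks
racing within the year — not a discrete-ordering approximation — which makes
the closed form directly checkable against simulation. The package ships that
simulation (`monte_carlo_probability()`): subjects are walked year by year,
drawing competing exponential event times, and the fracture fraction is
returned. The two routes agree within Monte-Carlo error on randomised hazard
paths in the test suite (20 paths at $10^6$ draws, a 3-standard-error bound).

Numerical conventions:

* a year with $f_i + d_i = 0$ contributes zero probability and leaves $S$
  unchanged (the analytic limit of the expression above);
* fracture-first, death-first and event-free-survival probabilities sum to 1
  to $10^{-12}$, and the tests assert this conservation;
* "fracture probability" means a *first* fracture of the given type before
  death within the horizon; re-fractures are not modelled;
* one-year steps reconcile 5-year input bands with a 10-year horizon starting
  at any integer age: year $i$ reads the rate band containing
  `start_age + i - 1`.

## Rate tables and their semantics

Tables are banded by age, half-open `[start, end)`, contiguous and
non-overlapping per sex, with an optional open-ended last band. Three rules
are deliberate:

* **Below the first band the model is undefined** (an error, not zero): the
  intended domain starts at age 50, and silently returning 0 would fabricate
  risk-free youth.
* **Beyond the last band the hazard is held constant** rather than
  extrapolated — conservative, and it avoids inventing extreme-old-age
  dynamics the inputs do not contain.
* Incidence is carried externally as events per 100,000 person-years (the
  scale at which fracture incidence is published) and converted to
  per-person-year hazards internally; mortality is an annual hazard in
  [0, 2) directly.

Writers serialise at 17 significant digits so read/write round-trips are
exact; validation raises typed conditions (`surrofrax_structural_error`,
`surrofrax_value_error`, `surrofrax_format_error`, ...) naming the offending
band.

## The risk-factor layer

Six dichotomous clinical risk factors act multiplicatively on the fracture
hazard; femoral-neck BMD enters as
$\mathrm{gradient}^{(T_{\mathrm{ref}} - T)}$ per SD of T-score (term = 1 when
BMD is unknown). Death hazards are never adjusted. The shipped defaults are
**placeholders, not calibrated coefficients** — authentic tools use
age-dependent, interaction-adjusted values that are not public — and every
number is configurable through `risk_factor_model()` or the YAML run
configuration:

| parameter | default | unit |
|---|---|---|
| prior fracture | 1.9 | HR |
| parental hip fracture | 1.8 | HR |
| current smoking | 1.5 | HR |
| glucocorticoids | 1.9 | HR |
| rheumatoid arthritis | 1.6 | HR |
| high alcohol intake | 1.6 | HR |
| gradient of risk, hip | 1.8 | HR per SD |
| gradient of risk, MOF | 1.6 | HR per SD |
| reference T-score | 0 | SD |
| BMI | 26 (recorded only) | kg/m² |

Two design points deserve explanation.

**MOF dominance constrains the defaults.** Because hip fracture is one of the
four MOF sites, a model should never report a hip probability above its MOF
probability. With MOF incidence imputed as hip × ratio (ratios ≥ 1, falling
to ≈ 2 in extreme old age), dominance of the *adjusted* hazards holds for
every profile only if the hip/MOF multiplier skew stays below the smallest
ratio. The defaults therefore share one CRF set across outcomes and differ
only in the BMD gradient (1.8 vs 1.6, a maximum skew of
$1.125^{3.5} \approx 1.51 < 2$). Users overriding coefficients can break this
guarantee; the dominance property is asserted in the test suite for the
defaults.

**BMI is recorded, not used.** Comparison grids fix BMI at a single value for
all profiles, so a BMI term would cancel in every contrast; published
grid-comparison work varies between 25 and 26 kg/m² for this constant — the
default here is 26, overridable per profile. A hazard effect of BMI is
deliberately out of scope for v1.

`enumerate_grid()` builds the full factorial array — not a population sample
— of $2^k$ factor combinations × T-score levels per age: six factors and
eight T-scores (0 to −3.5 SD in 0.5 steps) give 512 profiles per age, with
deterministic ordering (T-score outer, binary counter inner).

## MOF imputation

`impute_mof_incidence()` multiplies each hip band by the ratio applying at
the band's start age. The packaged ratio fixture falls from 6 at age 50 to 2
at 85+, the shape repeatedly observed where full MOF registration exists; it
is a synthetic stand-in with the right structure, not anyone's measured
values, and real analyses should supply their own table. Coverage is checked
band-by-band and a missing ratio band is a hard error.

## Comparing two models

`compare_models()` reports Pearson $r$, ordinary least squares of surrogate
on donor (with intercept — the published convention says "linear regression"
without further detail, and an intercept lets slope shifts and level shifts
be read separately), and Spearman $\rho$. The Spearman coefficient carries
the clinically decisive message: $\rho \approx 1$ means a subject's risk
percentile is the same under either model, so the surrogate re-scales
absolute probabilities without re-ordering anyone. Zero variance on either
side makes $r$ undefined and raises a typed comparison error rather than
returning `NaN`.

## Burden projection

Expected fracture counts are band-wise products, count × rate / 100,000,
restricted to bands starting at age 50+ (the model's domain) and priced at
the band midpoint. Incidence is held fixed at baseline for all projection
years — projections isolate the demographic effect. Counts are expected
values (no Poisson noise) and are rounded only at report time. The
"Increase (%)" row is defined as $100 \times$ (year total / baseline total),
rounded — so a year matching baseline reads 100, and 339 means a 3.4-fold
total. This matches the arithmetic of published burden tables of this form
(e.g. totals 6,897 → 23,409 give 339); note it is a ratio in percent, not a
percent *change*.

## The synthetic-data module

Both adult mortality and hip-fracture incidence rise roughly exponentially
with age, so the generators use a Gompertz form: band rate
$= r_{50}\,e^{\beta(\mathrm{mid}-50)}$, with a female:male multiplier.
The canonical fixture (`make_country_pair()`) encodes the study situation the
pipeline targets:

* donor hip incidence $r_{50}=15$/100k, $\beta=0.11$/yr, female = 2 × male —
  about 30/100k at 50 and 1,000/100k at 82 in women, the magnitude published
  for the South-Asian populations this kind of surrogate serves;
* index mortality $(0.0045, 0.098)$ vs donor mortality $(0.003, 0.095)$,
  females at 0.55 × male — an old-age mortality contrast of ≈ 1.7, inside
  the 1.5–2 band that motivates a surrogate in the first place;
* a bottom-heavy population pyramid whose older bands grow faster
  (25–75 % per decade), emulating medium-variant growth-plus-ageing.

These choices are fixed once; band-level log-normal jitter exists for
robustness experiments but is off by default so all examples are
deterministic. On this fixture the package reproduces the qualitative
signature expected of a sound surrogate: the donor-minus-surrogate
probability gap widens with age, grid Pearson $r > 0.995$ and Spearman
$\rho > 0.99$ at ages 50–80 for both outcomes and sexes. The agreement is
sensitive to the mortality contrast: pushing the contrast to the top of the
plausible band (≈ 2×) with high incidence drags the age-80 Pearson $r$ to
≈ 0.991, because both models' worst grid corners saturate near probability 1
and the relation bends — the rank concordance stays above 0.9999 throughout.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: cohort and secular trends in incidence,
sub-national and ethnic heterogeneity, non-Gompertz old-age mortality
plateaus, registration artefacts, and any real country's absolute rates. The
fixture validates structure and mechanics, not national estimates.

## Problem sizes in the tests

The suite exercises the full 512-profile grid at ages 50–80 for both sexes
and outcomes, Monte-Carlo verification at $10^6$ draws per path (20 paths),
and 100-case randomised monotonicity sweeps; the whole suite runs in well
under a minute. These sizes were chosen as the smallest that exercise every
contract at meaningful precision.

## Known limitations

* Post-fracture excess mortality is not modelled; absolute probabilities for
  high-risk elderly subjects are therefore slightly conservative relative to
  tools that model it.
* Risk-factor effects are constant over age and free of interactions.
* The MOF ratio fixture and CRF coefficients are placeholders; substantive
  use requires country-appropriate tables and published coefficient sets.
* Hazards are held constant beyond the last table band, which understates
  very-old-age mortality growth.
* No parametric survival fitting, covariate–time interactions, or sub-year
  hazard structure.
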