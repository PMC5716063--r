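---
title: "Design-based processing of stationary point count reef fish surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based processing of stationary point count reef fish surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefspc)
```

## The survey and its data

Large-scale coral reef monitoring programs in the tropical Pacific census
fish assemblages with stationary point counts (SPC): a pair of divers
simultaneously survey adjacent, visually estimated 15-m diameter cylindrical
plots laid out along a 30-m transect, recording every taxon seen with its
count and estimated total length (cm), an observation-type code, and a rapid
visual assessment of the benthos (percent cover, substrate height bins,
urchin abundance). One data row is one size/count observation of one taxon
by one diver in one cylinder. The sampling design is stratified: the survey
domain is all hard-bottom substrate shallower than 30 m, divided per island
(or pooled island group, or island sector) into reef zones (forereef,
backreef, lagoon, protected slope) crossed with depth bins — shallow
(0–6 m), mid (6–18 m) and deep (18–30 m).

`reefspc` implements the full processing chain for these data: schema
validation, observation-type filtering, allometric biomass conversion,
pair-then-site aggregation, design-based stratified estimation with
hard-bottom area weights, survey-effort allocation, observer quality
control, and a synthetic survey generator with known ground truth.

## From observations to site metrics

Individual fish weight uses the allometric model
$W = a\,(cL)^b$,
with $W$ in grams, $L$ the estimated total length in cm, $a, b$ the
species' length-weight constants, and $c$ a length-conversion factor that
rescales total length into the length form (fork or standard length) the
constants were fitted in. The factor is applied to $L$ *before*
exponentiation — the published column description defines it as a conversion
of the length, not of the resulting weight. Cylinder densities divide summed
counts and summed weights by the plot area $\pi (7.5\,\mathrm{m})^2 \approx
176.7\,\mathrm{m}^2$; the protocol fixes only the diameter, so the geometry
object is configurable for reuse with other plot sizes.

Observation types control which rows are density data. Instantaneous (`I`)
and non-instantaneous (`N`) records are pooled by default for density
reporting; `F` and `T` (species first seen 5–10 and 10–30 minutes into the
survey) can be added for questions about rarer, more mobile species; `P`
(present in the vicinity) is presence-only and the code refuses to pass it
to any density computation.

Adjacent cylinders are not independent replicates, so the site visit is the
sample unit: metrics are averaged within each SPC-pair and then between
pairs (with the usual single pair of two divers this is the plain mean of
the two cylinders). Site richness is reported as the mean of replicate
richness values — consistent with every other metric's averaging — with the
union count across replicates (`richness_union`) as a secondary metric,
since the field convention for richness is not fully explicit. The site
depth bin is recomputed from the midpoint between the minimum and maximum
replicate depths and cross-checked against the recorded label. Benthic
fields missing on one replicate are dropped at each averaging stage rather
than imputed.

## Stratified estimation

Within stratum $i$, the mean of site values $X_i$ is estimated with
variance $\mathrm{VAR}_i = s_i^2 / n_i$, where $s_i^2$ is the unbiased
among-site sample variance — simple random sampling within the stratum,
without a finite-population correction. The correction is deliberately
omitted: sites are a vanishing fraction of the hard-bottom area, and
omitting it is conservative. Strata pool to the reporting unit with
area-proportional weights $w_i = A_i / \sum_j A_j$ over the *sampled*
strata:

$$X = \sum_i^S X_i w_i, \qquad \mathrm{VAR} = \sum_i^S \mathrm{VAR}_i w_i^2.$$

When mapped strata were unsampled the weights renormalize over the sampled
ones and the estimate covers the sampled domain only. Strata with a single
site contribute their mean; their inestimable variance is imputed as the
mean stratum-mean variance of the unit's other strata (the count of
imputations is reported), or kept null under the `strict` option, in which
case the pooled variance is reported as missing.

Beyond the two pooling equations the package reports Satterthwaite
effective degrees of freedom,
$\mathrm{df} = \mathrm{VAR}^2 \big/ \sum_i (w_i^2 \mathrm{VAR}_i)^2/(n_i-1)$
over the strata with $n_i \ge 2$, and t-based 95% bounds. With 20–50 sites
per reporting unit the variance estimate itself is noisy, and a plain
$\pm 1.96\,\mathrm{SE}$ interval runs one to two points below nominal
coverage; the t interval restores calibration and is the convention of
design-based survey software.

Survey effort allocation is Neyman-style: target sites (generally 30–50 per
reef area) are split proportional to $A_h s_h$ — stratum area times the
among-site standard deviation of the target metric — with largest-remainder
rounding, ties broken by larger area then lexicographic stratum key.

## Validation rules and classifiers

Record-level rules follow the field protocol: observation codes in
`{I,N,F,T,P}` (`F`/`T` only from 2012 onwards), positive counts and sizes,
cylinder-centre depth within [1.5, 30] m (sites shallower than 1.5 m are
not surveyed; 30 m is the safe-diving limit), horizontal visibility within
(0, 30] m with surveys below 7.5 m not conducted (rejection is strictly
below: 7.5 m itself is surveyable), and percent-cover and substrate-height
vectors closing to 100 ± 0.5. A depth-bin label disagreeing with the
classified depth is a warning rather than an error, since the label is
derived metadata. The error/warning split is this package's own convention;
the protocol states rules but not enforcement semantics.

Two boundary conventions required a decision. The printed depth zones share
endpoints (0–6, 6–18, 18–30), so bins are lower-closed/upper-open with the
deepest closed at 30 — a deterministic total classification. The urchin
DACOR scales leave one integer unassigned (5 for free urchins, between
"R: <5" and "O: 6–20"; 25 for boring urchins); both close toward the rarer
class, giving R ≤ 5 and R ≤ 25. The ordinal complexity score is accepted on
1–6 as the published column description states, although the narrative
protocol mentions a five-point scale; the schema follows the column
description. Substrate-height summaries use bin midpoints
{0.10, 0.35, 0.75, 1.25, 1.75} m; the open top bin (">1.5 m") has no
printed representative height, and 1.75 m assumes an effective 1.5–2 m span
(configurable). The ordinal-to-height conversion is an ordinary least
squares fit exposed in both directions, because the published convention
does not fix one; calibration pairs must be supplied externally.

## The synthetic generator and what passing tests mean

`simulate_survey()` emits records in the published dialect with the full
hierarchy: stratum → site → SPC-pair → two diver replicates → species
observations. Per site and species, a latent count is drawn negative
binomial (mean = species baseline × stratum multiplier, dispersion `size`
parameter) and a latent length lognormal truncated at the species' maximum
length. Each diver observes the *same* latent state through independent
error: counts are re-drawn Poisson with a mean-one lognormal factor
(`count_error_sd`), sizes get additive Gaussian error
(`size_error_sd_cm`, default 0.5 cm). Zero error short-circuits to the
latent values exactly, which gives the noiseless end-to-end contract its
meaning. `F`/`T`/`P` rows are generated as *extra* sightings beyond the
latent instantaneous community, so the default `I`+`N` filter recovers the
latent truth exactly — the generator's formalization of what the
observation types mean for density.

Ground truth comes in two forms, both computed by direct arithmetic on the
latent state, independent of the package's aggregation code:
`truth$expected`, the analytic means implied by the generating parameters
(the expected per-fish weight uses the closed-form partial moment of the
truncated lognormal), and `truth$realized`, the area-weighted means of the
latent site values actually drawn. A noiseless survey processed through
write → read → filter → site → stratum → pool must reproduce the realized
truth to 10⁻⁹ (it does, to ~10⁻¹⁵); repeated noisy surveys must recover the
expected truth.

Defaults describe a Saipan-like reef area: backreef and lagoon (shallow)
plus a forereef split across three depth bins using the published
hard-bottom areas (598, 3539 and 583 ha, the forereef split evenly across
bins since per-bin areas are not published), six sites per stratum
(30 sites, the low end of a routine island visit), a 20-species pool, and
one SPC-pair of two divers per site. Sizes are generated continuous rather
than rounded to the nearest cm as divers record them; this keeps the
analytic truth exact, and the sub-centimeter distinction is far below
observer sizing error.

The estimator's Monte Carlo calibration uses a separate fixed configuration,
`mc_validation_config()`: two forereef strata of 10 sites each and a
species-rich, moderately dispersed community (40 species, dispersion 50,
narrow size spread). These conditions make site-level biomass close to
Gaussian, so interval coverage measures the estimator rather than
small-sample skew — with 10 sites per stratum and a heavy-tailed community,
no variance estimator yields calibrated nominal intervals, and a coverage
check would be testing the central limit theorem instead. At 1,000
replicate surveys the pooled mean is unbiased to well under 1% and the
t-based 95% interval covers the analytic truth at ~0.95.

What the generator does *not* emulate: spatial autocorrelation among sites,
fish movement and diver avoidance or attraction, species detectability
differences, inter-diver identification disagreement, and the operational
constraints that shape real site allocation. Passing tests therefore
demonstrate that the processing chain is correct and the estimator
well-calibrated *under the stated sampling model*; they do not validate the
field protocol itself against those sources of bias.

## Problem sizes and numerics

The test suite and the acceptance script run the noiseless exactness check
on one 30-site survey, the Monte Carlo calibration on 500–1,000 replicate
20-site surveys (a few tens of seconds), and property checks on randomized
fixtures of a few hundred rows — sizes chosen so the full validation runs
in well under a minute while leaving Monte Carlo error far inside the
tolerances checked. Weight vectors are validated to sum to 1 within 10⁻⁹;
density additivity and the two-stage mean are exact to floating point; CSV
round-trips preserve reals to better than 10⁻⁶ (values are written with
full precision).

## Known limitations

Sectors are supported as reporting-unit subdivisions carrying their own
strata — pooling sectors to island scale reuses the same two equations with
sector-area weights — but no sector boundary definitions ship with the
package. Depth-zone pre-pooling for backreef and lagoon zones (routine in
some reporting) is available by passing an area table without a `depth_bin`
column, but is off by default. The shipped hard-bottom area table carries
reef-zone resolution only; per-depth-bin areas within zones must be
supplied by the user for finer-grained weighting. Latitude and longitude
are carried through untouched; the package does no geodesy, no species-name
resolution against external registries, and no model-based (geostatistical)
estimation.
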