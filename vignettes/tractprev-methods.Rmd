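---
title: "Methods: EHR-based tract prevalence surveillance and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR-based tract prevalence surveillance and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tractprev` implements a surveillance pipeline that turns multi-system
electronic health record (EHR) extracts into census-tract denominators and
chronic disease prevalence estimates, and compares those against
census population counts and model-based small-area estimates. This
vignette documents the underlying procedures, the assumptions they make,
the tunable parameters, and the choices taken where the design was
genuinely open. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## The measurement problem

A census-tract prevalence estimate needs a numerator (who has the
condition) and a denominator (who lives there). EHR networks and surveys
disagree on both. The EHR denominator is the *care-seeking* population —
everyone with an encounter at a participating system in a lookback
window — which may be smaller or larger than the census count of a
stratum (larger, for example, when the census undercounts a group that
does seek care). The EHR numerator is a *computable phenotype*: a
deterministic rule over codes, vitals and labs, with sensitivity below 1
for true disease. Model-based survey estimates (CDC PLACES-style) instead
extrapolate sparse self-reported survey responses through a small-area
model. The package quantifies, on data where truth is known, how each of
these mechanisms moves tract-level estimates.

## Linkage and reporting-system assignment

Persons are linked across systems by exact match on an opaque identity
hash, the output of privacy-preserving record linkage. The package takes
those hashes as given (collision-free at the scales simulated) and does
no probabilistic matching.

Each linked person is assigned to the single system with the most
**distinct encounter dates** in the 3-calendar-year window ending
December 31 of the index year. Two decisions here were open and are fixed
as follows:

- *Frequency of care* counts distinct encounter days, not raw encounter
  rows, so duplicate same-day rows (common in real extracts) cannot
  change an assignment.
- *Ties* go to the lexicographically smallest system id. Any fixed rule
  would do; this one is deterministic and invariant to input row order,
  which the test suite verifies by brute force over permuted inputs.

Demographic conflicts resolve to the assigned system's value (that system
is the reporting source of record), falling back to the most recent
non-missing value by address date; geography takes the most recent
address record as a unit, on the view that residence should reflect the
latest known location even if that record lacks a geocoded tract.

## Eligibility and phenotypes

For index year $Y$, a person is eligible if alive on December 31 of $Y$,
meets the age condition on that date (inclusive — turning 18 on
December 31 qualifies; `min_age = NULL` yields the all-ages population
used for denominator comparisons), and has ≥1 encounter at the assigned
system in $Y-2 \dots Y$.

All lookbacks are **whole calendar years** anchored at December 31: the
"last 3 years" for 2020 is 2018–2020. Anchoring to each person's last
encounter instead was considered and rejected: calendar anchoring makes
annual surveillance tables reproducible from frozen yearly extracts.

The phenotypes are disjunctions, evaluated over events pooled across all
of a person's systems:

- **Hypertension**: ≥1 hypertension code in $Y-4 \dots Y$, *or*
  qualifying outpatient blood pressure on ≥2 distinct days in
  $Y-2 \dots Y$. A reading qualifies if SBP ≥ 140 mm Hg or DBP ≥ 90 mm Hg
  *within the same reading*; a day qualifies if any outpatient reading
  that day qualifies. Missing components are non-qualifying, never
  errors.
- **Diabetes**: ≥1 diabetes code in $Y-4 \dots Y$, *or* ≥1 HbA1c ≥ 6.5%
  (inclusive) in $Y-2 \dots Y$.

Whether same-day SBP and DBP recorded as separate rows should be merged
before thresholding is left unmerged: each stored reading is evaluated
as-is, which is conservative (it can only miss combinations, not invent
them) and matches how OMOP measurement rows arrive. Both phenotypes are
monotone in the event history — adding events can only turn a flag on —
and the suite checks equivalence against a brute-force oracle on
randomized histories of up to ~50 events.

## Geography

Persons without a geocoded tract are allocated through a zip-to-tract
crosswalk whose weights are population ratios (the semantics of the HUD
ZIP–TRACT residential ratio). Two modes exist because the aggregation
target differs:

- **fractional** (default): the person contributes the weight vector
  itself, so tract counts are expectations and total counts are conserved
  *exactly* — the right choice for prevalence tables.
- **sampled**: one tract per person, for person-level outputs. The draw
  uses a uniform deviate derived by hashing the person's identity hash
  with the seed, not the global RNG stream, so results are reproducible
  and independent of row order.

Zips missing from the crosswalk land in an explicit unassigned bucket
rather than being dropped, keeping the conservation identity
`sum(tract counts) + unassigned = cohort size` exact.

## Comparison statistics

Stratum ratios are plain count ratios `n_EHR / n_census`; coverage is
`100 · n_EHR / n_census`. Concordance between an EHR and a reference
tract table uses the relative difference
$(p_{EHR} - p_{ref}) / p_{ref}$, with the reference (model-based) source
in the denominator and **inclusive** band boundaries: a tract exactly 10%
off counts as within 10%. Bland–Altman components are the per-tract
difference $p_{EHR} - p_{ref}$ against the pair mean, with limits of
agreement at mean ± 1.96·SD. Tracts present in only one source, or with
zero reference prevalence, are excluded and itemized rather than silently
dropped.

Display rounding is half-up (away from zero): 2 decimals for ratios,
1 decimal for percentages — the convention of published surveillance
tables, and the reason `round_half_up()` exists instead of base
`round()`'s half-to-even. Machine outputs always retain unrounded
values; rounding is applied only in `*_display` columns and printed
summaries.

County summaries and SVI quartiles both use the type-7
(linear-interpolation) quantile definition. SVI quartile boundaries are
closed on the right, so a tract tied with a boundary falls in the lower
(less vulnerable) quartile; constant input degenerates to quartile 1 with
a warning rather than an error, since a pipeline step should not die on a
pathological but interpretable input.

## Tract covariate models

`fit_prevalence_model()` is ordinary least squares of tract prevalence
(0–100 scale) on percentage covariates (population over 65, Black,
American Indian/Alaska Native, Asian/Hawaiian-Pacific-Islander shares,
poverty, high-school attainment — all 0–100, so coefficients are
percentage points of prevalence per percentage point of covariate) and
dummy-coded SVI quartile (reference: quartile 1) and urbanicity
(reference: urban). Standard errors are normal-theory and non-robust:
the model assumes independence across census tracts, and spatial
correlation will understate uncertainty — coefficient estimates remain
unbiased. Robust or spatially correlated errors are deliberately out of
scope. Rank-deficient designs error with the collinear terms named
instead of silently dropping them.

## What the synthetic generator emulates — and what it does not

The generator's defaults define the study conditions the package is
tested under:

| Parameter | Default | Rationale |
|---|---|---|
| `n_systems` | 11 | the statewide-consortium scale being emulated |
| `index_year` | 2020 | census comparison year; windows 2018–2020 |
| `demographic_mix` | MN-like margins, crossed | age 23/35/25/17%, sex ~50/50, race 76/7/6/5/1/5% |
| `care_seeking` | varies by age, sex, race | reproduces stratum ratios ≠ 1 (women and elders higher, AI/AN and Hispanic lower) |
| `multi_system_prob` | 0.15 | overlap rates are unpublished; uniform shares and a modest overlap are arbitrary, documented choices |
| `dx_sensitivity` | 0.85 | diagnosis codes miss true cases; vitals/labs recover some |
| `measurement_rates` | bp 0.7, a1c 0.25 | BP taken at most visits, HbA1c ordered selectively |
| `prevalence_coefs` | published-magnitude associations | tracts get realistic covariate-prevalence structure |
| `places_noise_sd` | 1.5 pp | model-based estimates scatter around truth |
| `places_bias` | 0 | bias is a knob, unbiased by default |
| `geocode_success_prob` | 0.95 | a small un-geocoded fraction exercises the crosswalk |
| `census_undercount` | 1.0 | census equals truth exactly unless the undercount mechanism is under study |

True condition status is drawn per adult at the tract's expected
prevalence, a linear function of realized tract covariates; the recorded
tract truth is the realized person-level mean, so truth-recovery tests
can demand exact equality. Hypertensive persons always emit qualifying
readings and normotensive persons strictly sub-threshold ones, which lets
tests isolate the distinct-day rule from measurement noise.

The generator deliberately does **not** emulate: longitudinal disease
onset and resolution; real code dictionaries (a single condition token
stands for the code list); inpatient/outpatient mix (all generated BP
rows are outpatient — tests inject inpatient rows explicitly);
out-migration and mortality (death handling exists in the eligibility
rules but the generator emits no deaths by default); hash collisions; and
the survey small-area model itself, which is consumed as truth + bias +
noise, never re-estimated. Passing tests therefore show the *pipeline's*
correctness and the *mechanisms'* effects under controlled conditions —
not that real EHR data share these distributions.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at 3,000–25,000 persons and checks
stratum-ratio recovery at 100,000 persons across 150 tracts, sizes at
which binomial error on a stratum ratio is a few tenths of a percentage
point while the suite stays fast. OLS recovery uses 300 tracts:
noiseless outcomes must reproduce coefficients to 1e-8 (numerical
exactness of the least-squares solve), and across 200 noisy replicates
the 95% CIs must cover the generating coefficients at least 90% of the
time. Determinism checks demand byte-identical serialized output for
identical configurations. Statistical assertions use intervals derived
from the binomial or normal error of the quantity itself (e.g. a 99%
binomial interval for sampled crosswalk shares), never ad-hoc slack.

## Known limitations

- Exact-match linkage only; real consortia handle hash collisions and
  near-matches, which this package treats as out of scope.
- The generator's independence assumptions (demographics crossed
  independently, conditions independent given tract) understate the
  correlation structure of real populations.
- OLS inference ignores spatial autocorrelation, as noted above.
- The crosswalk is single-vintage; tract boundary changes across census
  years are not converted.
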