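# Published statewide aggregates (Minnesota, 2020-2022)

Small plain-text tables of publicly reported aggregate counts used by the
worked examples and by `scripts/acceptance.R`. They contain no person-level
data.

- `mn_population_table.csv` — 2020 Minnesota EHR Consortium (MNEHRC)
  patient counts and 2020 census population estimates by sex/race and age
  group. Feeding these through `ratio_table()` reproduces the published
  coverage ratios (e.g. female 0.97, Black 1.17).
- `mn_statewide_totals.csv` — statewide 2020 MNEHRC patient total and
  census total (coverage 92.4%). The sex rows of the population table sum
  to slightly less than the statewide census total (persons of unknown sex
  are not broken out in the published table).
- `mn_prevalence_pairs.csv` — published adult numerator/denominator pairs
  for diabetes (2022) and hypertension (2021) from MNEHRC and from the CDC
  PLACES crude totals.
- `mn_concordance_counts.csv` — published counts of census tracts whose
  EHR-derived estimate fell within 10% / 25% of the PLACES estimate, out
  of 1500 tracts.
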