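test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config(seed = 11)
  a <- sim_study(cfg)
  b <- sim_study(cfg)
  expect_identical(serialize(a$population, NULL), serialize(b$population, NULL))
  expect_identical(serialize(a$ehr, NULL), serialize(b$ehr, NULL))
  expect_identical(serialize(a$places, NULL), serialize(b$places, NULL))
  # a different seed changes the draw
  expect_false(identical(sim_population(small_config(seed = 12)), a$population))
})

test_that("stratum counts follow the demographic mix and sum to n_persons", {
  mix <- tidyr::expand_grid(
    age_group = c("18-44", "45-64"), sex = c("female", "male"),
    race_ethnicity = "white"
  )
  mix$prop <- 0.25
  cfg <- sim_config(
    seed = 3, n_persons = 1000, n_tracts = 10,
    demographic_mix = mix, care_seeking = always_care(mix)
  )
  pop <- sim_population(cfg)
  counts <- table(pop$persons$age_group, pop$persons$sex)
  expect_equal(sum(counts), 1000)
  # each stratum has expectation 250; allow 4 binomial SDs (~55)
  expect_true(all(abs(counts - 250) < 55))
})

test_that("census is the exact cross-tabulation of truth when undercount is 1", {
  pop <- sim_population(small_config(seed = 5))
  truth_tab <- pop$persons |>
    dplyr::count(.data$tract_id, .data$age_group, .data$sex,
      .data$race_ethnicity,
      name = "true_n"
    )
  joined <- dplyr::left_join(
    pop$census, truth_tab,
    by = c("tract_id", "age_group", "sex", "race_ethnicity")
  ) |>
    dplyr::mutate(true_n = dplyr::coalesce(.data$true_n, 0L))
  expect_equal(joined$census_n, as.numeric(joined$true_n))
  expect_equal(sum(pop$census$census_n), small_config()$n_persons)
})

test_that("per-stratum undercount factors scale the census multiplicatively", {
  uc <- tibble::tibble(race_ethnicity = "black", undercount = 0.9)
  cfg1 <- small_config(seed = 5)
  cfg2 <- small_config(seed = 5, census_undercount = uc)
  c1 <- sim_population(cfg1)$census
  c2 <- sim_population(cfg2)$census
  black <- c1$race_ethnicity == "black"
  expect_equal(c2$census_n[black], c1$census_n[black] * 0.9)
  expect_equal(c2$census_n[!black], c1$census_n[!black])
})

test_that("tract truth prevalence equals the person-level mean exactly", {
  pop <- sim_population(small_config(seed = 9))
  chk <- pop$persons |>
    dplyr::filter(.data$age >= 18) |>
    dplyr::group_by(.data$tract_id) |>
    dplyr::summarise(p = 100 * mean(.data$hypertension_true), .groups = "drop")
  joined <- dplyr::inner_join(pop$tract_truth, chk, by = "tract_id")
  expect_equal(joined$hypertension_prev_pct, joined$p)
})

test_that("crosswalk weights are population ratios summing to 1 per zip", {
  pop <- sim_population(small_config(seed = 2))
  sums <- tapply(pop$crosswalk$weight, pop$crosswalk$zip_code, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("care seekers appear in exactly one system when multi-system visits are off", {
  cfg <- small_config(
    seed = 21, care_seeking = always_care(), multi_system_prob = 0
  )
  st <- sim_study(cfg)
  per_person <- table(st$ehr$persons$identity_hash)
  expect_true(all(per_person == 1))
  expect_equal(length(per_person), cfg$n_persons)
  # every person has at least one in-window encounter
  yrs <- as.integer(format(st$ehr$encounters$encounter_date, "%Y"))
  expect_true(all(yrs >= 2018 & yrs <= 2020))
})

test_that("distinct identity keys across systems equal the care-seeking count", {
  st <- sim_study(small_config(seed = 23))
  expect_equal(
    dplyr::n_distinct(st$ehr$persons$identity_hash),
    sum(st$ehr$care$care_seeker)
  )
})

test_that("no emitted codes or measurements mean zero downstream prevalence", {
  cfg <- small_config(
    seed = 31, dx_sensitivity = 0,
    measurement_rates = list(bp = 0, a1c = 0)
  )
  st <- sim_study(cfg)
  expect_equal(nrow(st$ehr$conditions), 0)
  expect_equal(nrow(st$ehr$bp), 0)
  cohort <- build_cohort(st, cfg$index_year)
  expect_equal(sum(cohort$hypertension), 0)
  expect_equal(sum(cohort$diabetes), 0)
})

test_that("perfect sensitivity, care-seeking and geocoding recover truth exactly", {
  cfg <- small_config(
    seed = 37, care_seeking = always_care(), dx_sensitivity = 1,
    geocode_success_prob = 1
  )
  st <- sim_study(cfg)
  cohort <- build_cohort(st, cfg$index_year, min_age = 18)
  # person-level identity via brute-force join of truth to cohort
  truth <- st$population$persons |> dplyr::filter(.data$age >= 18)
  joined <- dplyr::inner_join(
    truth |>
      dplyr::select("identity_hash", "hypertension_true", "diabetes_true"),
    cohort, by = "identity_hash"
  )
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$hypertension, joined$hypertension_true)
  expect_equal(joined$diabetes, joined$diabetes_true)

  res <- resolve_tracts(cohort, st$population$crosswalk)
  for (cond in c("hypertension", "diabetes")) {
    tp <- tract_prevalence(res, cond)
    chk <- dplyr::inner_join(
      tp, st$population$tract_truth,
      by = "tract_id"
    )
    expect_equal(chk$denominator, as.numeric(chk$n_adults))
    expect_equal(chk$numerator, as.numeric(chk[[paste0(cond, "_cases")]]))
  }
})

test_that("model-based estimates are truth plus bias plus clipped noise", {
  cfg0 <- small_config(seed = 41, places_noise_sd = 0, places_bias = 0)
  pop <- sim_population(cfg0)
  pl0 <- sim_places(cfg0, pop)
  truth <- tidyr::pivot_longer(
    pop$tract_truth |>
      dplyr::filter(.data$n_adults > 0) |>
      dplyr::select("tract_id",
        hypertension = "hypertension_prev_pct",
        diabetes = "diabetes_prev_pct"
      ),
    -"tract_id",
    names_to = "condition", values_to = "truth_pct"
  )
  j0 <- dplyr::inner_join(pl0, truth, by = c("tract_id", "condition"))
  expect_equal(j0$prevalence_pct, j0$truth_pct)

  cfg2 <- small_config(seed = 41, places_noise_sd = 0, places_bias = 2)
  j2 <- dplyr::inner_join(
    sim_places(cfg2, pop), truth,
    by = c("tract_id", "condition")
  )
  expect_equal(j2$prevalence_pct, j2$truth_pct + 2)
})

test_that("noise SD is recovered empirically across 500 tracts", {
  cfg <- sim_config(
    seed = 43, n_persons = 25000, n_tracts = 500, places_noise_sd = 1
  )
  pop <- sim_population(cfg)
  pl <- sim_places(cfg, pop)
  truth <- tidyr::pivot_longer(
    pop$tract_truth |>
      dplyr::filter(.data$n_adults > 0) |>
      dplyr::select("tract_id",
        hypertension = "hypertension_prev_pct",
        diabetes = "diabetes_prev_pct"
      ),
    -"tract_id",
    names_to = "condition", values_to = "truth_pct"
  )
  j <- dplyr::inner_join(pl, truth, by = c("tract_id", "condition"))
  emp_sd <- sd(j$prevalence_pct - j$truth_pct)
  expect_gt(emp_sd, 0.8)
  expect_lt(emp_sd, 1.2)
})
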