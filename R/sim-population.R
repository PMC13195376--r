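#' Generate the synthetic statewide population and its geography
#'
#' Builds, under the configuration seed, a person-level truth table (one
#' tract, one sex, one mutually exclusive race/ethnicity category, and one
#' birth date per person), tract covariates, per-tract true prevalence for
#' hypertension and diabetes, the census cross-tabulation of the truth
#' population (optionally perturbed by a per-stratum undercount factor),
#' and a zip-to-tract crosswalk whose weights are the realized population
#' ratios.
#'
#' True condition status is assigned only to adults: a tract's expected
#' prevalence is a linear function of its realized covariates (age
#' structure, race composition, SVI quartile, urbanicity, poverty,
#' education), and each adult is a Bernoulli draw at that tract's expected
#' value. The recorded per-tract true prevalence is the realized
#' person-level mean, so it matches the indicators exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `persons`, `tracts`, `tract_truth`,
#'   `census`, `crosswalk`.
#' @export
sim_population <- function(config) {
  stopifnot(inherits(config, "tractprev_config"))
  withr::with_seed(config$seed, sim_population_impl(config))
}

sim_population_impl <- function(config) {
  n_tracts <- config$n_tracts
  n <- config$n_persons
  ref <- dec31(config$index_year)

  # --- geography: tracts nested in counties, zips spanning 1-2 tracts ---
  n_counties <- max(1L, as.integer(round(n_tracts / 17)))
  n_zips <- max(1L, as.integer(ceiling(n_tracts * 0.6)))
  tracts <- tibble::tibble(
    tract_id = sprintf("T%04d", seq_len(n_tracts)),
    county_id = sprintf("C%03d", sort(rep_len(seq_len(n_counties), n_tracts))),
    zip_code = sprintf("55%03d", ceiling(seq_len(n_tracts) * n_zips / n_tracts)),
    pct_below_poverty = 100 * stats::rbeta(n_tracts, 2, 18),
    pct_hs_or_ged = 100 * stats::rbeta(n_tracts, 30, 3),
    urbanicity = sample(
      c("urban", "exurban", "rural", "small_town"),
      n_tracts,
      replace = TRUE, prob = c(0.45, 0.20, 0.20, 0.15)
    )
  )
  # latent social vulnerability, correlated with poverty
  if (n_tracts >= 4) {
    z <- as.numeric(scale(tracts$pct_below_poverty))
    z[is.na(z)] <- 0
    tracts$svi_cont <- stats::pnorm(0.6 * z + 0.8 * stats::rnorm(n_tracts))
    tracts$svi_quartile <- svi_quartiles(tracts$svi_cont)
  } else {
    tracts$svi_cont <- stats::runif(n_tracts)
    tracts$svi_quartile <- factor(rep(1, n_tracts), levels = 1:4)
  }

  # --- persons: stratum from the mix, tract conditional on race ---
  mix <- config$demographic_mix
  stratum <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$prop)
  age_lo <- c("0-17" = 0L, "18-44" = 18L, "45-64" = 45L, "65+" = 65L)
  age_hi <- c("0-17" = 17L, "18-44" = 44L, "45-64" = 64L, "65+" = 94L)
  grp <- mix$age_group[stratum]
  age <- age_lo[grp] +
    floor(stats::runif(n) * (age_hi[grp] - age_lo[grp] + 1L))
  # birth date consistent with integer age on Dec 31 of the index year:
  # Dec 31 (index_year - age) minus 0..364 days always yields that age
  birth_date <- ref - lubridate::years(as.integer(age)) -
    lubridate::days(sample.int(365L, n, replace = TRUE) - 1L)

  size_w <- stats::rgamma(n_tracts, shape = 8)
  size_w <- size_w / sum(size_w)
  tilt <- list(
    black = exp(stats::rnorm(n_tracts, 0, 1)),
    hispanic = exp(stats::rnorm(n_tracts, 0, 1)),
    aian = exp(stats::rnorm(n_tracts, 0, 1.2)),
    asian_hpi = exp(stats::rnorm(n_tracts, 0, 1)),
    white = rep(1, n_tracts),
    other = rep(1, n_tracts)
  )
  race <- mix$race_ethnicity[stratum]
  tract_idx <- integer(n)
  for (r in unique(race)) {
    i <- which(race == r)
    p <- size_w * tilt[[r]]
    tract_idx[i] <- sample.int(n_tracts, length(i), replace = TRUE, prob = p)
  }

  persons <- tibble::tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    age = as.integer(age),
    age_group = mix$age_group[stratum],
    sex = mix$sex[stratum],
    race_ethnicity = race,
    birth_date = birth_date,
    tract_id = tracts$tract_id[tract_idx],
    county_id = tracts$county_id[tract_idx],
    zip_code = tracts$zip_code[tract_idx]
  )
  salt <- sprintf("tractprev-%d", config$seed)
  key <- paste(persons$person_id, format(persons$birth_date), sep = "|")
  persons$identity_hash <- paste0(
    fnv1a_hash(key, salt = paste0(salt, "-a")),
    fnv1a_hash(key, salt = paste0(salt, "-b"))
  )
  persons <- dplyr::left_join(
    persons, config$care_seeking,
    by = c("age_group", "sex", "race_ethnicity")
  )

  # --- realized tract covariates from the population itself ---
  comp <- persons |>
    dplyr::count(.data$tract_id, name = "n_all")
  comp <- tracts |>
    dplyr::select("tract_id") |>
    dplyr::left_join(comp, by = "tract_id") |>
    dplyr::mutate(n_all = dplyr::coalesce(.data$n_all, 0L))
  pct_by <- function(flag) {
    persons |>
      dplyr::filter(flag) |>
      dplyr::count(.data$tract_id, name = "k") |>
      dplyr::right_join(comp, by = "tract_id") |>
      dplyr::mutate(
        pct = ifelse(.data$n_all > 0,
          100 * dplyr::coalesce(.data$k, 0L) / .data$n_all, 0
        )
      ) |>
      dplyr::arrange(.data$tract_id) |>
      dplyr::pull(.data$pct)
  }
  tracts <- tracts |>
    dplyr::arrange(.data$tract_id) |>
    dplyr::mutate(
      pct_over_65 = pct_by(persons$age >= 65),
      pct_black = pct_by(persons$race_ethnicity == "black"),
      pct_aian = pct_by(persons$race_ethnicity == "aian"),
      pct_asian_hpi = pct_by(persons$race_ethnicity == "asian_hpi")
    )

  # --- expected and realized true prevalence ---
  for (cond in c("hypertension", "diabetes")) {
    b <- config$prevalence_coefs[[cond]]
    lp <- b["intercept"] +
      b["pct_over_65"] * tracts$pct_over_65 +
      b["pct_black"] * tracts$pct_black +
      b["pct_aian"] * tracts$pct_aian +
      b["pct_asian_hpi"] * tracts$pct_asian_hpi +
      b["svi2"] * (tracts$svi_quartile == 2) +
      b["svi3"] * (tracts$svi_quartile == 3) +
      b["svi4"] * (tracts$svi_quartile == 4) +
      b["exurban"] * (tracts$urbanicity == "exurban") +
      b["rural"] * (tracts$urbanicity == "rural") +
      b["small_town"] * (tracts$urbanicity == "small_town") +
      b["pct_below_poverty"] * tracts$pct_below_poverty +
      b["pct_hs_or_ged"] * tracts$pct_hs_or_ged
    tracts[[paste0(substr(cond, 1, 3), "_prev_expected")]] <-
      pmin(pmax(unname(lp), 0.5), 95)
  }

  adult <- persons$age >= 18
  p_hyp <- tracts$hyp_prev_expected[match(persons$tract_id, tracts$tract_id)]
  p_dia <- tracts$dia_prev_expected[match(persons$tract_id, tracts$tract_id)]
  persons$hypertension_true <- adult &
    (stats::runif(nrow(persons)) < p_hyp / 100)
  persons$diabetes_true <- adult &
    (stats::runif(nrow(persons)) < p_dia / 100)

  tract_truth <- persons |>
    dplyr::group_by(.data$tract_id) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      n_adults = sum(.data$age >= 18),
      hypertension_cases = sum(.data$hypertension_true),
      diabetes_cases = sum(.data$diabetes_true),
      .groups = "drop"
    ) |>
    dplyr::right_join(tracts |> dplyr::select("tract_id"), by = "tract_id") |>
    dplyr::mutate(dplyr::across(
      c("n_persons", "n_adults", "hypertension_cases", "diabetes_cases"),
      ~ dplyr::coalesce(.x, 0L)
    )) |>
    dplyr::mutate(
      hypertension_prev_pct = ifelse(.data$n_adults > 0,
        100 * .data$hypertension_cases / .data$n_adults, NA_real_
      ),
      diabetes_prev_pct = ifelse(.data$n_adults > 0,
        100 * .data$diabetes_cases / .data$n_adults, NA_real_
      )
    ) |>
    dplyr::arrange(.data$tract_id)

  census <- build_census(persons, tracts, config$census_undercount)
  crosswalk <- build_crosswalk(persons, tracts)

  list(
    persons = persons, tracts = tracts, tract_truth = tract_truth,
    census = census, crosswalk = crosswalk
  )
}

# Exact cross-tabulation of the truth population by tract and stratum,
# multiplied by the per-stratum undercount factor (default 1 = identity).
build_census <- function(persons, tracts, undercount) {
  census <- persons |>
    dplyr::count(
      .data$tract_id, .data$age_group, .data$sex, .data$race_ethnicity,
      name = "true_n"
    ) |>
    tidyr::complete(
      tract_id = tracts$tract_id,
      age_group = c("0-17", "18-44", "45-64", "65+"),
      sex = c("female", "male"),
      race_ethnicity = c(
        "white", "black", "hispanic", "asian_hpi", "aian", "other"
      ),
      fill = list(true_n = 0L)
    )
  if (is.data.frame(undercount)) {
    by <- intersect(
      c("tract_id", "age_group", "sex", "race_ethnicity"),
      names(undercount)
    )
    census <- census |>
      dplyr::left_join(undercount, by = by) |>
      dplyr::mutate(undercount = dplyr::coalesce(.data$undercount, 1))
  } else {
    census$undercount <- undercount
  }
  census |>
    dplyr::mutate(census_n = .data$true_n * .data$undercount) |>
    dplyr::select(
      "tract_id", "age_group", "sex", "race_ethnicity", "census_n"
    ) |>
    dplyr::left_join(
      tracts |> dplyr::select("tract_id", "county_id"),
      by = "tract_id"
    ) |>
    dplyr::arrange(
      .data$tract_id, .data$age_group, .data$sex, .data$race_ethnicity
    )
}

# Zip-to-tract weights are realized population ratios; an unpopulated zip
# falls back to a uniform split over its tracts. Weights per zip sum to 1.
build_crosswalk <- function(persons, tracts) {
  pop <- persons |>
    dplyr::count(.data$tract_id, name = "pop")
  tracts |>
    dplyr::select("zip_code", "tract_id") |>
    dplyr::left_join(pop, by = "tract_id") |>
    dplyr::mutate(pop = dplyr::coalesce(.data$pop, 0L)) |>
    dplyr::group_by(.data$zip_code) |>
    dplyr::mutate(
      weight = if (sum(.data$pop) > 0) {
        .data$pop / sum(.data$pop)
      } else {
        rep(1 / dplyr::n(), dplyr::n())
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("zip_code", "tract_id", "weight") |>
    dplyr::arrange(.data$zip_code, .data$tract_id)
}
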