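#' Default demographic mix for the synthetic statewide population
#'
#' A full cross of four age groups, two sexes, and the six mutually
#' exclusive race/ethnicity categories used in consortium-census
#' comparisons (Hispanic, and non-Hispanic American Indian or Alaska
#' Native; Asian or Hawaiian/Pacific Islander; Black; White; other).
#' Marginal proportions approximate the 2020 Minnesota population; the
#' three margins are crossed independently.
#'
#' @return A tibble with columns `age_group`, `sex`, `race_ethnicity`,
#'   `prop` summing to 1.
#' @export
default_demographic_mix <- function() {
  age <- c("0-17" = 0.23, "18-44" = 0.35, "45-64" = 0.25, "65+" = 0.17)
  sex <- c(female = 0.503, male = 0.497)
  race <- c(
    white = 0.762, black = 0.069, hispanic = 0.061,
    asian_hpi = 0.053, aian = 0.010, other = 0.045
  )
  g <- tidyr::expand_grid(
    age_group = names(age), sex = names(sex), race_ethnicity = names(race)
  )
  g$prop <- age[g$age_group] * sex[g$sex] * race[g$race_ethnicity]
  g
}

#' Default care-seeking probabilities by demographic stratum
#'
#' The probability that a person has at least one encounter at any
#' consortium system during the three-year lookback window. Defaults vary
#' by age, sex, and race/ethnicity so that EHR-to-census stratum ratios
#' deviate from 1 in the directions observed in statewide surveillance
#' (higher for women and older adults, lower for American Indian and
#' Hispanic residents).
#'
#' @param mix A demographic mix tibble (see [default_demographic_mix()]);
#'   only its stratum columns are used.
#' @return The mix tibble with a `care_prob` column in `[0, 1]`.
#' @export
default_care_seeking <- function(mix = default_demographic_mix()) {
  age_base <- c("0-17" = 0.83, "18-44" = 0.93, "45-64" = 0.90, "65+" = 0.97)
  sex_mult <- c(female = 1.045, male = 0.955)
  race_mult <- c(
    white = 1.00, black = 1.05, hispanic = 0.80,
    asian_hpi = 0.92, aian = 0.72, other = 1.00
  )
  mix |>
    dplyr::select("age_group", "sex", "race_ethnicity") |>
    dplyr::mutate(care_prob = pmin(
      age_base[.data$age_group] * sex_mult[.data$sex] *
        race_mult[.data$race_ethnicity],
      0.99
    ))
}

#' Default tract-covariate coefficients for true prevalence
#'
#' Linear coefficients (percentage-point scale) linking tract covariates to
#' the expected true prevalence in a tract, one set per condition. Values
#' are set to magnitudes typical of published tract-level associations for
#' hypertension and diabetes (age structure dominating, social
#' vulnerability and non-urban residence adding a few points, education
#' protective), so the synthetic state has realistic covariate-prevalence
#' structure.
#'
#' @return Named list with `hypertension` and `diabetes` coefficient
#'   vectors.
#' @export
default_prevalence_coefs <- function() {
  list(
    hypertension = c(
      intercept = 41, pct_over_65 = 0.54, pct_black = -0.10,
      pct_aian = -0.12, pct_asian_hpi = -0.08,
      svi2 = 1.62, svi3 = 2.19, svi4 = 2.53,
      exurban = 4.16, rural = 4.25, small_town = 5.98,
      pct_below_poverty = -0.05, pct_hs_or_ged = -0.23
    ),
    diabetes = c(
      intercept = 20.5, pct_over_65 = 0.14, pct_black = 0.01,
      pct_aian = 0.07, pct_asian_hpi = 0.02,
      svi2 = 0.86, svi3 = 1.51, svi4 = 1.88,
      exurban = 1.00, rural = 2.29, small_town = 1.93,
      pct_below_poverty = -0.01, pct_hs_or_ged = -0.16
    )
  )
}

#' Configuration for the synthetic study generator
#'
#' Bundles and validates every knob of the synthetic data generator: the
#' population size and geography, the demographic mix, care-seeking and
#' multi-system probabilities, diagnosis-code sensitivity, per-visit
#' measurement capture rates, the covariate-to-prevalence coefficients,
#' the noise/bias of the model-based (PLACES-like) estimates, geocoding
#' success, and a per-stratum census undercount factor.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   output tables.
#' @param n_persons Number of persons in the true statewide population.
#' @param n_tracts Number of census tracts.
#' @param n_systems Number of health systems sharing the population
#'   (default 11, the consortium scale the generator emulates).
#' @param index_year Calendar year anchoring all lookback windows
#'   (eligibility: encounters in `index_year - 2 .. index_year`).
#' @param demographic_mix Tibble of `(age_group, sex, race_ethnicity, prop)`
#'   summing to 1 within 1e-9.
#' @param care_seeking Tibble mapping strata to `care_prob` in `[0, 1]`.
#' @param multi_system_prob Probability a care-seeker also visits a second
#'   system.
#' @param mean_encounters Mean number of encounters (beyond the guaranteed
#'   first) at the primary system over the 3-year window.
#' @param dx_sensitivity Probability a true case carries a diagnosis code.
#' @param measurement_rates Named list: per-encounter probability of a blood
#'   pressure reading (`bp`) and an HbA1c result (`a1c`).
#' @param prevalence_coefs Per-condition covariate coefficients, see
#'   [default_prevalence_coefs()].
#' @param places_bias Additive bias (percentage points) of the model-based
#'   estimates relative to truth.
#' @param places_noise_sd Standard deviation (percentage points) of their
#'   noise; must be nonnegative.
#' @param geocode_success_prob Probability a person's address geocodes to a
#'   tract; failures carry only a zip code.
#' @param census_undercount Multiplicative per-stratum census factor: either
#'   a scalar (default 1 = census equals truth exactly) or a tibble with
#'   stratum columns and an `undercount` column.
#' @return A validated list of class `tractprev_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_persons = 20000,
                       n_tracts = 100,
                       n_systems = 11,
                       index_year = 2020,
                       demographic_mix = default_demographic_mix(),
                       care_seeking = default_care_seeking(demographic_mix),
                       multi_system_prob = 0.15,
                       mean_encounters = 3,
                       dx_sensitivity = 0.85,
                       measurement_rates = list(bp = 0.7, a1c = 0.25),
                       prevalence_coefs = default_prevalence_coefs(),
                       places_bias = 0,
                       places_noise_sd = 1.5,
                       geocode_success_prob = 0.95,
                       census_undercount = 1) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_persons >= 1, n_tracts >= 1, n_systems >= 1,
    index_year >= 1900, index_year <= 9999
  )
  if (abs(sum(demographic_mix$prop) - 1) > 1e-9) {
    stop("demographic_mix proportions must sum to 1 (within 1e-9), got ",
      format(sum(demographic_mix$prop), digits = 12),
      call. = FALSE
    )
  }
  if (any(demographic_mix$prop < 0)) {
    stop("demographic_mix proportions must be nonnegative", call. = FALSE)
  }
  probs <- c(
    care_seeking$care_prob, multi_system_prob, dx_sensitivity,
    measurement_rates$bp, measurement_rates$a1c, geocode_success_prob
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (places_noise_sd < 0) stop("places_noise_sd must be >= 0", call. = FALSE)
  if (mean_encounters < 0) stop("mean_encounters must be >= 0", call. = FALSE)
  missing_strata <- dplyr::anti_join(
    demographic_mix, care_seeking,
    by = c("age_group", "sex", "race_ethnicity")
  )
  if (nrow(missing_strata) > 0) {
    stop("care_seeking is missing ", nrow(missing_strata),
      " strata present in demographic_mix",
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_persons = as.integer(n_persons),
      n_tracts = as.integer(n_tracts), n_systems = as.integer(n_systems),
      index_year = as.integer(index_year),
      demographic_mix = demographic_mix, care_seeking = care_seeking,
      multi_system_prob = multi_system_prob,
      mean_encounters = mean_encounters,
      dx_sensitivity = dx_sensitivity,
      measurement_rates = measurement_rates,
      prevalence_coefs = prevalence_coefs,
      places_bias = places_bias, places_noise_sd = places_noise_sd,
      geocode_success_prob = geocode_success_prob,
      census_undercount = census_undercount
    ),
    class = "tractprev_config"
  )
}

#' @export
print.tractprev_config <- function(x, ...) {
  cat("<tractprev_config>\n")
  cat(sprintf(
    "  %s persons, %d tracts, %d systems, index year %d, seed %d\n",
    format(x$n_persons, big.mark = ","), x$n_tracts, x$n_systems,
    x$index_year, x$seed
  ))
  cat(sprintf(
    "  dx sensitivity %.2f, geocode success %.2f, places noise sd %.2f\n",
    x$dx_sensitivity, x$geocode_success_prob, x$places_noise_sd
  ))
  invisible(x)
}
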