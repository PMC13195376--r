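#' Generate per-system EHR tables from the truth population
#'
#' Emulates a statewide network of overlapping health systems mapped to a
#' common data model. Each care-seeking person (a Bernoulli draw at the
#' stratum care-seeking probability) receives a primary system uniformly
#' at random and at least one encounter there within the 3-calendar-year
#' window ending December 31 of the index year; with probability
#' `multi_system_prob` the person also visits a second system under the
#' same identity hash. True cases emit a condition-code row with
#' probability `dx_sensitivity` (dated within the 5-calendar-year window)
#' and emit qualifying blood-pressure / HbA1c values at the per-encounter
#' measurement rates; non-cases emit strictly non-qualifying values. A
#' fraction `1 - geocode_success_prob` of persons carry only a zip code.
#'
#' @param config A [sim_config()] object.
#' @param population Output of [sim_population()] under the same config.
#' @return A list of tibbles: `persons` (one row per person per system),
#'   `encounters`, `conditions`, `bp`, `a1c`, and `care` (per-person
#'   care-seeking truth: probability, realized indicator, primary system).
#' @export
sim_ehr <- function(config, population) {
  stopifnot(inherits(config, "tractprev_config"))
  withr::with_seed(config$seed + 1L, sim_ehr_impl(config, population))
}

sim_ehr_impl <- function(config, population) {
  yr <- config$index_year
  persons <- population$persons
  n <- nrow(persons)
  systems <- sprintf("S%02d", seq_len(config$n_systems))

  seeker <- stats::runif(n) < persons$care_prob
  care <- tibble::tibble(
    person_id = persons$person_id,
    identity_hash = persons$identity_hash,
    care_prob = persons$care_prob,
    care_seeker = seeker
  )
  sp <- persons[seeker, ]
  ns <- nrow(sp)
  primary <- sample(systems, ns, replace = TRUE)
  care$primary_system <- NA_character_
  care$primary_system[seeker] <- primary

  multi <- if (config$n_systems > 1) {
    stats::runif(ns) < config$multi_system_prob
  } else {
    rep(FALSE, ns)
  }
  # second system drawn uniformly among the others
  second <- rep(NA_character_, ns)
  if (any(multi)) {
    shift <- sample.int(config$n_systems - 1L, sum(multi), replace = TRUE)
    second[multi] <- systems[
      (match(primary[multi], systems) - 1L + shift) %% config$n_systems + 1L
    ]
  }

  visits <- dplyr::bind_rows(
    tibble::tibble(
      row = seq_len(ns), system_id = primary,
      n_enc = 1L + stats::rpois(ns, config$mean_encounters)
    ),
    tibble::tibble(
      row = which(multi), system_id = second[multi],
      n_enc = 1L + stats::rpois(sum(multi), max(config$mean_encounters / 4, 0.2))
    )
  )

  window_days <- seq(jan1(yr - 2L), dec31(yr), by = "day")
  enc_row <- rep(seq_len(nrow(visits)), visits$n_enc)
  encounters <- tibble::tibble(
    identity_hash = sp$identity_hash[visits$row[enc_row]],
    system_id = visits$system_id[enc_row],
    encounter_date = sample(window_days, length(enc_row), replace = TRUE)
  )

  geo_ok <- stats::runif(ns) < config$geocode_success_prob
  addr_date <- encounters |>
    dplyr::group_by(.data$identity_hash, .data$system_id) |>
    dplyr::summarise(address_date = max(.data$encounter_date), .groups = "drop")
  ehr_persons <- tibble::tibble(
    identity_hash = sp$identity_hash[visits$row],
    system_id = visits$system_id,
    birth_date = sp$birth_date[visits$row],
    sex = sp$sex[visits$row],
    race_ethnicity = sp$race_ethnicity[visits$row],
    tract_id = ifelse(geo_ok[visits$row], sp$tract_id[visits$row],
      NA_character_
    ),
    zip_code = sp$zip_code[visits$row]
  ) |>
    dplyr::left_join(addr_date, by = c("identity_hash", "system_id")) |>
    dplyr::arrange(.data$system_id, .data$identity_hash)

  # condition-code rows for true cases, at the configured sensitivity,
  # dated anywhere in the 5-calendar-year lookback, filed at the primary
  dx_days <- seq(jan1(yr - 4L), dec31(yr), by = "day")
  emit_dx <- function(flag, token) {
    has <- flag[visits$row] & visits$system_id == primary[visits$row]
    idx <- which(has)
    idx <- idx[stats::runif(length(idx)) < config$dx_sensitivity]
    tibble::tibble(
      identity_hash = sp$identity_hash[visits$row[idx]],
      system_id = visits$system_id[idx],
      condition = token,
      condition_date = sample(dx_days, length(idx), replace = TRUE)
    )
  }
  conditions <- dplyr::bind_rows(
    emit_dx(sp$hypertension_true, "hypertension"),
    emit_dx(sp$diabetes_true, "diabetes")
  ) |>
    dplyr::arrange(.data$identity_hash, .data$condition, .data$condition_date)

  # vitals and labs captured per encounter; hypertensives always read at or
  # above threshold, normotensives strictly below; likewise for HbA1c
  htn <- sp$hypertension_true[visits$row[enc_row]]
  take_bp <- stats::runif(length(enc_row)) < config$measurement_rates$bp
  bp <- tibble::tibble(
    identity_hash = encounters$identity_hash[take_bp],
    system_id = encounters$system_id[take_bp],
    measurement_date = encounters$encounter_date[take_bp],
    sbp = ifelse(htn[take_bp],
      stats::runif(sum(take_bp), 142, 185),
      stats::runif(sum(take_bp), 100, 135)
    ),
    dbp = ifelse(htn[take_bp],
      stats::runif(sum(take_bp), 70, 100),
      stats::runif(sum(take_bp), 60, 85)
    ),
    outpatient = TRUE
  )

  dm <- sp$diabetes_true[visits$row[enc_row]]
  take_a1c <- stats::runif(length(enc_row)) < config$measurement_rates$a1c
  a1c <- tibble::tibble(
    identity_hash = encounters$identity_hash[take_a1c],
    system_id = encounters$system_id[take_a1c],
    measurement_date = encounters$encounter_date[take_a1c],
    a1c = ifelse(dm[take_a1c],
      stats::runif(sum(take_a1c), 6.5, 11),
      stats::runif(sum(take_a1c), 4.8, 6.2)
    )
  )

  list(
    persons = ehr_persons,
    encounters = encounters |>
      dplyr::arrange(.data$system_id, .data$identity_hash, .data$encounter_date),
    conditions = conditions, bp = bp, a1c = a1c, care = care
  )
}

#' Generate model-based (PLACES-like) tract prevalence estimates
#'
#' Small-area model-based estimates are consumed as an input by the
#' comparison stage, never re-estimated; this generator emulates them as
#' truth plus configurable bias plus Gaussian noise, clipped to `[0, 100]`,
#' with the tract adult population as the denominator column.
#'
#' @param config A [sim_config()] object.
#' @param population Output of [sim_population()] under the same config.
#' @return A tibble `(tract_id, condition, prevalence_pct, denominator)`;
#'   tracts with no adults are omitted.
#' @export
sim_places <- function(config, population) {
  stopifnot(inherits(config, "tractprev_config"))
  withr::with_seed(config$seed + 2L, {
    tt <- population$tract_truth |>
      dplyr::filter(.data$n_adults > 0)
    tidyr::pivot_longer(
      tt |>
        dplyr::select(
          "tract_id", "n_adults",
          hypertension = "hypertension_prev_pct",
          diabetes = "diabetes_prev_pct"
        ),
      cols = c("hypertension", "diabetes"),
      names_to = "condition", values_to = "truth_pct"
    ) |>
      dplyr::mutate(
        prevalence_pct = pmin(pmax(
          .data$truth_pct + config$places_bias +
            stats::rnorm(dplyr::n(), 0, config$places_noise_sd),
          0
        ), 100),
        denominator = .data$n_adults
      ) |>
      dplyr::select("tract_id", "condition", "prevalence_pct", "denominator")
  })
}

#' Generate a complete synthetic study input set
#'
#' Convenience wrapper running [sim_population()], [sim_ehr()] and
#' [sim_places()] under one configuration. Identical configurations give
#' byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `config`, `population`, `ehr`, `places`.
#' @export
sim_study <- function(config) {
  population <- sim_population(config)
  ehr <- sim_ehr(config, population)
  places <- sim_places(config, population)
  list(config = config, population = population, ehr = ehr, places = places)
}
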