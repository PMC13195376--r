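#' Computable phenotype rule
#'
#' Thresholds and lookback windows for the rule-based hypertension and
#' diabetes phenotypes. All lookbacks are whole calendar years ending
#' December 31 of the index year ("last 5 years" for an index year Y means
#' calendar years Y-4 through Y), and all thresholds are inclusive.
#'
#' Hypertension: at least one hypertension condition code in the last
#' 5 years, or an elevated outpatient blood pressure (systolic >= 140 mm Hg
#' or diastolic >= 90 mm Hg on the same reading) on 2 or more distinct days
#' in the last 3 years. Diabetes: at least one diabetes condition code in
#' the last 5 years, or at least one HbA1c value >= 6.5 percent in the last
#' 3 years.
#'
#' @param condition `"hypertension"` or `"diabetes"`.
#' @param dx_lookback_years Calendar years of condition-code lookback
#'   (default 5).
#' @param measure_lookback_years Calendar years of vitals/labs lookback
#'   (default 3).
#' @param sbp_threshold,dbp_threshold Inclusive blood-pressure cutoffs in
#'   mm Hg (defaults 140 / 90).
#' @param bp_min_distinct_days Minimum number of distinct qualifying
#'   outpatient BP days (default 2).
#' @param a1c_threshold Inclusive HbA1c cutoff in percent (default 6.5).
#' @param a1c_min_count Minimum number of qualifying HbA1c results
#'   (default 1).
#' @return A list of class `phenotype_rule`.
#' @export
phenotype_rule <- function(condition = c("hypertension", "diabetes"),
                           dx_lookback_years = 5L,
                           measure_lookback_years = 3L,
                           sbp_threshold = 140,
                           dbp_threshold = 90,
                           bp_min_distinct_days = 2L,
                           a1c_threshold = 6.5,
                           a1c_min_count = 1L) {
  condition <- match.arg(condition)
  stopifnot(dx_lookback_years >= 1, measure_lookback_years >= 1)
  structure(
    list(
      condition = condition,
      dx_lookback_years = as.integer(dx_lookback_years),
      measure_lookback_years = as.integer(measure_lookback_years),
      sbp_threshold = sbp_threshold, dbp_threshold = dbp_threshold,
      bp_min_distinct_days = as.integer(bp_min_distinct_days),
      a1c_threshold = a1c_threshold, a1c_min_count = as.integer(a1c_min_count)
    ),
    class = "phenotype_rule"
  )
}

year_in <- function(date, index_year, lookback_years) {
  y <- lubridate::year(date)
  y >= index_year - lookback_years + 1L & y <= index_year
}

#' Flag persons meeting the hypertension phenotype
#'
#' @param conditions Condition-occurrence tibble (`identity_hash`,
#'   `condition`, `condition_date`).
#' @param bp Blood-pressure tibble (`identity_hash`, `measurement_date`,
#'   `sbp`, `dbp`, `outpatient`); missing components are non-qualifying.
#' @param index_year Index calendar year.
#' @param rule A [phenotype_rule()] (default hypertension rule).
#' @return Tibble `(identity_hash, hypertension)` listing every hash that
#'   satisfies the phenotype (flag always `TRUE`; absent hashes are
#'   negative).
#' @export
flag_hypertension <- function(conditions, bp, index_year,
                              rule = phenotype_rule("hypertension")) {
  dx_hit <- conditions |>
    dplyr::filter(
      .data$condition == "hypertension",
      year_in(.data$condition_date, index_year, rule$dx_lookback_years)
    ) |>
    dplyr::distinct(.data$identity_hash)

  bp_hit <- bp |>
    dplyr::filter(
      dplyr::coalesce(.data$outpatient, FALSE),
      year_in(.data$measurement_date, index_year, rule$measure_lookback_years),
      dplyr::coalesce(.data$sbp >= rule$sbp_threshold, FALSE) |
        dplyr::coalesce(.data$dbp >= rule$dbp_threshold, FALSE)
    ) |>
    dplyr::distinct(.data$identity_hash, .data$measurement_date) |>
    dplyr::count(.data$identity_hash, name = "n_days") |>
    dplyr::filter(.data$n_days >= rule$bp_min_distinct_days) |>
    dplyr::select("identity_hash")

  dplyr::bind_rows(dx_hit, bp_hit) |>
    dplyr::distinct(.data$identity_hash) |>
    dplyr::arrange(.data$identity_hash) |>
    dplyr::mutate(hypertension = TRUE)
}

#' Flag persons meeting the diabetes phenotype
#'
#' @param conditions Condition-occurrence tibble.
#' @param a1c HbA1c tibble (`identity_hash`, `measurement_date`, `a1c`,
#'   percent units).
#' @param index_year Index calendar year.
#' @param rule A [phenotype_rule()] (default diabetes rule).
#' @return Tibble `(identity_hash, diabetes)` listing every qualifying
#'   hash.
#' @export
flag_diabetes <- function(conditions, a1c, index_year,
                          rule = phenotype_rule("diabetes")) {
  dx_hit <- conditions |>
    dplyr::filter(
      .data$condition == "diabetes",
      year_in(.data$condition_date, index_year, rule$dx_lookback_years)
    ) |>
    dplyr::distinct(.data$identity_hash)

  lab_hit <- a1c |>
    dplyr::filter(
      year_in(.data$measurement_date, index_year, rule$measure_lookback_years),
      dplyr::coalesce(.data$a1c >= rule$a1c_threshold, FALSE)
    ) |>
    dplyr::count(.data$identity_hash, name = "n_labs") |>
    dplyr::filter(.data$n_labs >= rule$a1c_min_count) |>
    dplyr::select("identity_hash")

  dplyr::bind_rows(dx_hit, lab_hit) |>
    dplyr::distinct(.data$identity_hash) |>
    dplyr::arrange(.data$identity_hash) |>
    dplyr::mutate(diabetes = TRUE)
}

#' Apply eligibility rules to assigned persons
#'
#' A person is eligible for a given index year if they are alive on
#' December 31 of that year (a `death_date` column, when present, excludes
#' persons who died on or before that date), meet the age condition on that
#' date (inclusive: a person turning `min_age` on December 31 qualifies;
#' `min_age = NULL` keeps all ages, as population-count analyses do), and
#' have at least one encounter at their assigned system within the
#' 3-calendar-year window. Persons with a missing birth date cannot satisfy
#' an age condition and are excluded with a logged reason.
#'
#' @param assigned Output of [assign_reporting_system()].
#' @param encounters Encounter tibble.
#' @param index_year Index calendar year.
#' @param min_age Minimum age in whole years on December 31, or `NULL`.
#' @param lookback_years Encounter lookback window (default 3 calendar
#'   years).
#' @return `assigned` with logical `eligible` and character
#'   `exclusion_reason` (NA when eligible) columns.
#' @export
apply_eligibility <- function(assigned, encounters, index_year,
                              min_age = 18L, lookback_years = 3L) {
  ref <- dec31(index_year)

  has_enc <- encounters |>
    dplyr::filter(year_in(.data$encounter_date, index_year, lookback_years)) |>
    dplyr::distinct(.data$identity_hash, .data$system_id) |>
    dplyr::mutate(has_inwindow = TRUE)
  out <- assigned |>
    dplyr::left_join(
      has_enc,
      by = c("identity_hash", assigned_system = "system_id")
    ) |>
    dplyr::mutate(has_inwindow = dplyr::coalesce(.data$has_inwindow, FALSE))

  alive <- if ("death_date" %in% names(out)) {
    is.na(out$death_date) | out$death_date > ref
  } else {
    rep(TRUE, nrow(out))
  }

  if (is.null(min_age)) {
    age_ok <- rep(TRUE, nrow(out))
    missing_bd <- rep(FALSE, nrow(out))
  } else {
    missing_bd <- is.na(out$birth_date)
    age_ok <- !missing_bd & age_on(out$birth_date, ref) >= min_age
    if (any(missing_bd)) {
      message(
        sum(missing_bd),
        " person(s) excluded: missing birth date with an age condition set"
      )
    }
  }

  out |>
    dplyr::mutate(
      eligible = alive & age_ok & .data$has_inwindow,
      exclusion_reason = dplyr::case_when(
        !alive ~ "deceased",
        missing_bd ~ "missing_birth_date",
        !age_ok ~ "below_min_age",
        !.data$has_inwindow ~ "no_inwindow_encounter",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(-"has_inwindow")
}

#' Build a phenotype-flagged cohort for an index year
#'
#' Runs linkage, eligibility, and both phenotypes end to end: one row per
#' eligible person with demographics, geography, and hypertension/diabetes
#' flags. Phenotype events are evaluated across all systems a person
#' visited (linkage pools the person's record), while the eligibility
#' encounter must be at the assigned system.
#'
#' @param ehr A list of EHR tibbles (`$persons`, `$encounters`,
#'   `$conditions`, `$bp`, `$a1c`), e.g. `sim_study(cfg)$ehr` or real
#'   extracts with the same schema.
#' @param index_year Index calendar year.
#' @param min_age Minimum age (default 18 for prevalence analyses; `NULL`
#'   for all-ages population counts).
#' @return Cohort tibble: identity hash, assigned system, demographics
#'   (including derived `age` and `age_group`), tract/zip, logical
#'   `hypertension` and `diabetes` flags.
#' @export
build_cohort <- function(ehr, index_year, min_age = 18L) {
  if (!is.null(ehr$ehr)) ehr <- ehr$ehr # accept a full sim_study() result
  assigned <- link_ehr(ehr, index_year)
  elig <- apply_eligibility(
    assigned, ehr$encounters, index_year,
    min_age = min_age
  )
  cohort <- elig |>
    dplyr::filter(.data$eligible) |>
    dplyr::left_join(
      flag_hypertension(ehr$conditions, ehr$bp, index_year),
      by = "identity_hash"
    ) |>
    dplyr::left_join(
      flag_diabetes(ehr$conditions, ehr$a1c, index_year),
      by = "identity_hash"
    ) |>
    dplyr::mutate(
      hypertension = dplyr::coalesce(.data$hypertension, FALSE),
      diabetes = dplyr::coalesce(.data$diabetes, FALSE),
      age = age_on(.data$birth_date, dec31(index_year)),
      age_group = age_group_of(.data$age)
    ) |>
    dplyr::select(
      "identity_hash", "assigned_system", "birth_date", "age", "age_group",
      "sex", "race_ethnicity", "tract_id", "zip_code",
      "hypertension", "diabetes"
    )
  cohort
}
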