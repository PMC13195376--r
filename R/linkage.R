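#' Deduplicate person rows across health systems
#'
#' Persons are linked across systems by exact match on their opaque
#' identity hash (the product of privacy-preserving record linkage), so a
#' linked group is simply the set of per-system rows sharing one hash.
#' Exact duplicate `(identity_hash, system_id)` rows are collapsed with a
#' warning.
#'
#' @param persons Per-system person tibble with at least `identity_hash`
#'   and `system_id` columns.
#' @return The person tibble with duplicates collapsed and an added
#'   `n_systems` column (group size); one row per person per system.
#' @export
deduplicate_persons <- function(persons) {
  stopifnot(
    all(c("identity_hash", "system_id") %in% names(persons)),
    all(nzchar(persons$identity_hash))
  )
  dup <- duplicated(persons[, c("identity_hash", "system_id")])
  if (any(dup)) {
    warning(
      sum(dup), " duplicate (identity_hash, system_id) rows collapsed",
      call. = FALSE
    )
    persons <- persons[!dup, ]
  }
  persons |>
    dplyr::group_by(.data$identity_hash) |>
    dplyr::mutate(n_systems = dplyr::n()) |>
    dplyr::ungroup()
}

first_non_na <- function(x) {
  i <- which(!is.na(x))
  if (length(i) == 0) x[NA_integer_] else x[i[1]]
}

#' Assign each linked person to one reporting system
#'
#' Implements frequency-of-care assignment: every person is attributed to
#' the system where they had the most distinct encounter dates within the
#' 3-calendar-year window ending December 31 of `index_year`. Ties go to
#' the lexicographically smallest `system_id`, a deterministic,
#' order-invariant rule. Persons with no in-window encounter at any system
#' are retained with `assigned_system = NA` (they can never satisfy
#' eligibility, but remain available for audit).
#'
#' Demographic fields are taken from the assigned system's person row and,
#' where missing there, from the most recent non-missing value by address
#' date. Geography (tract, zip) is taken as a unit from the most recent
#' address record across all systems.
#'
#' @param persons Per-system person tibble (see [sim_ehr()] for the
#'   schema); passed through [deduplicate_persons()] first.
#' @param encounters Tibble with `identity_hash`, `system_id`,
#'   `encounter_date`.
#' @param index_year Index calendar year.
#' @return One row per distinct identity hash: `assigned_system`,
#'   `n_encounter_days` (distinct in-window dates at the assigned system),
#'   merged demographics and geography.
#' @export
assign_reporting_system <- function(persons, encounters, index_year) {
  persons <- deduplicate_persons(persons)

  in_window <- encounters |>
    dplyr::filter(
      lubridate::year(.data$encounter_date) >= index_year - 2L,
      lubridate::year(.data$encounter_date) <= index_year
    )
  day_counts <- in_window |>
    dplyr::distinct(.data$identity_hash, .data$system_id, .data$encounter_date) |>
    dplyr::count(.data$identity_hash, .data$system_id, name = "n_days")
  assigned <- day_counts |>
    dplyr::arrange(
      .data$identity_hash, dplyr::desc(.data$n_days), .data$system_id
    ) |>
    dplyr::distinct(.data$identity_hash, .keep_all = TRUE) |>
    dplyr::rename(
      assigned_system = "system_id", n_encounter_days = "n_days"
    )

  all_hashes <- tibble::tibble(
    identity_hash = sort(unique(persons$identity_hash))
  )
  assigned <- all_hashes |>
    dplyr::left_join(assigned, by = "identity_hash") |>
    dplyr::mutate(
      n_encounter_days = dplyr::coalesce(.data$n_encounter_days, 0L)
    )

  ranked <- persons |>
    dplyr::left_join(
      assigned |> dplyr::select("identity_hash", "assigned_system"),
      by = "identity_hash"
    ) |>
    dplyr::mutate(
      is_assigned = !is.na(.data$assigned_system) &
        .data$system_id == .data$assigned_system
    )

  has_addr_date <- "address_date" %in% names(persons)
  if (!has_addr_date) ranked$address_date <- as.Date(NA)

  demo <- ranked |>
    dplyr::arrange(
      .data$identity_hash, dplyr::desc(.data$is_assigned),
      dplyr::desc(!is.na(.data$address_date)), dplyr::desc(.data$address_date),
      .data$system_id
    ) |>
    dplyr::group_by(.data$identity_hash) |>
    dplyr::summarise(
      birth_date = first_non_na(.data$birth_date),
      sex = first_non_na(.data$sex),
      race_ethnicity = first_non_na(.data$race_ethnicity),
      .groups = "drop"
    )

  geo <- ranked |>
    dplyr::arrange(
      .data$identity_hash,
      dplyr::desc(!is.na(.data$address_date)), dplyr::desc(.data$address_date),
      dplyr::desc(.data$is_assigned), .data$system_id
    ) |>
    dplyr::group_by(.data$identity_hash) |>
    dplyr::summarise(
      tract_id = dplyr::first(.data$tract_id),
      zip_code = dplyr::first(.data$zip_code),
      .groups = "drop"
    )

  assigned |>
    dplyr::left_join(demo, by = "identity_hash") |>
    dplyr::left_join(geo, by = "identity_hash")
}

#' Link and assign a full multi-system EHR extract
#'
#' Convenience wrapper: deduplicates the person tables and runs
#' frequency-of-care assignment against the encounter tables.
#'
#' @param ehr A list of EHR tibbles as produced by [sim_ehr()] (uses
#'   `$persons` and `$encounters`).
#' @param index_year Index calendar year.
#' @return See [assign_reporting_system()].
#' @export
link_ehr <- function(ehr, index_year) {
  assign_reporting_system(ehr$persons, ehr$encounters, index_year)
}
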