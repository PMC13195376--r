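#' Resolve cohort persons to census tracts via a zip-to-tract crosswalk
#'
#' Persons with a geocoded tract keep it with weight 1. Persons with only
#' a zip code are allocated across the zip's tracts by the crosswalk's
#' population-ratio weights: in `"fractional"` mode (the default) a person
#' contributes fractional counts to every tract of the zip, which is
#' variance-free and conserves counts exactly; in `"sampled"` mode one
#' tract is drawn per person with the crosswalk weights, using a uniform
#' deviate derived from the person's identity hash and `seed`, so the draw
#' is seed-deterministic and invariant to row order. Persons whose zip is
#' absent from the crosswalk go to an explicit unassigned bucket
#' (`tract_id` NA, `unassigned = TRUE`) so that total counts are conserved.
#'
#' @param cohort Cohort tibble with `identity_hash`, `tract_id`,
#'   `zip_code`.
#' @param crosswalk Tibble `(zip_code, tract_id, weight)`; weights for each
#'   zip must sum to 1 within 1e-9.
#' @param mode `"fractional"` or `"sampled"`.
#' @param seed Integer seed for sampled mode.
#' @return The cohort with resolved `tract_id`, a `weight` column (1 except
#'   for fractional allocations), and logical `geocoded` and `unassigned`
#'   columns. In fractional mode an un-geocoded person occupies one row per
#'   candidate tract.
#' @export
resolve_tracts <- function(cohort, crosswalk,
                           mode = c("fractional", "sampled"), seed = 0L) {
  mode <- match.arg(mode)
  bad <- crosswalk |>
    dplyr::group_by(.data$zip_code) |>
    dplyr::summarise(s = sum(.data$weight), .groups = "drop") |>
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad) > 0) {
    stop(
      "crosswalk weights do not sum to 1 for zip(s): ",
      paste(utils::head(bad$zip_code, 5), collapse = ", "),
      call. = FALSE
    )
  }

  geocoded <- cohort |>
    dplyr::filter(!is.na(.data$tract_id)) |>
    dplyr::mutate(weight = 1, geocoded = TRUE, unassigned = FALSE)

  pending <- cohort |>
    dplyr::filter(is.na(.data$tract_id)) |>
    dplyr::mutate(geocoded = FALSE)
  known_zip <- pending$zip_code %in% crosswalk$zip_code
  unassigned <- pending[!known_zip, ] |>
    dplyr::mutate(weight = 1, unassigned = TRUE)
  pending <- pending[known_zip, ]

  allocated <- if (nrow(pending) == 0) {
    pending |> dplyr::mutate(weight = numeric(0), unassigned = logical(0))
  } else if (mode == "fractional") {
    pending |>
      dplyr::select(-"tract_id") |>
      dplyr::left_join(
        crosswalk,
        by = "zip_code", relationship = "many-to-many"
      ) |>
      dplyr::mutate(unassigned = FALSE)
  } else {
    cw <- crosswalk |>
      dplyr::arrange(.data$zip_code, .data$tract_id) |>
      dplyr::group_by(.data$zip_code) |>
      dplyr::mutate(cum_hi = cumsum(.data$weight)) |>
      dplyr::ungroup()
    u <- hash_unit(paste0(pending$identity_hash, ":", seed))
    pick <- vapply(seq_len(nrow(pending)), function(i) {
      rows <- cw[cw$zip_code == pending$zip_code[i], ]
      rows$tract_id[which(u[i] < rows$cum_hi + 1e-12)[1]]
    }, character(1))
    pending |>
      dplyr::mutate(tract_id = pick, weight = 1, unassigned = FALSE)
  }

  dplyr::bind_rows(geocoded, allocated, unassigned) |>
    dplyr::arrange(.data$identity_hash, .data$tract_id)
}

#' Aggregate a resolved cohort to tract-level prevalence estimates
#'
#' Sums (possibly fractional) person weights per tract: the denominator is
#' the total weight, the numerator the weight of persons with the
#' condition flag set.
#'
#' @param resolved Output of [resolve_tracts()].
#' @param condition Name of a logical cohort column (`"hypertension"` or
#'   `"diabetes"`).
#' @param source Label for the `source` column (default `"EHR"`).
#' @return Tibble `(tract_id, source, condition, numerator, denominator,
#'   prevalence_pct)`; persons in the unassigned bucket are reported under
#'   `tract_id = NA`, with `prevalence_pct` computed all the same.
#' @export
tract_prevalence <- function(resolved, condition, source = "EHR") {
  stopifnot(condition %in% names(resolved))
  resolved |>
    dplyr::group_by(.data$tract_id) |>
    dplyr::summarise(
      numerator = sum(.data$weight * .data[[condition]]),
      denominator = sum(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      source = source,
      condition = condition,
      prevalence_pct = prevalence_pct(.data$numerator, .data$denominator)
    ) |>
    dplyr::select(
      "tract_id", "source", "condition", "numerator", "denominator",
      "prevalence_pct"
    )
}
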