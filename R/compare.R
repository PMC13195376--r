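#' EHR-to-census count ratios by stratum
#'
#' Joins two stratum count tables and computes the EHR-to-census ratio per
#' stratum. A ratio near 1 means the care-seeking EHR population covers
#' the census population of that stratum; deviations from 1 quantify
#' differential capture (or census undercount).
#'
#' @param ehr_counts Tibble with the stratum columns in `by` and a count
#'   column `n`.
#' @param census_counts Same shape for the census source.
#' @param by Character vector of stratum columns to join on.
#' @return Tibble with `ehr_n`, `census_n`, unrounded `ratio`,
#'   `ratio_display` (2-decimal half-up), and `undefined` flagging strata
#'   with a zero census count (ratio NA).
#' @export
ratio_table <- function(ehr_counts, census_counts, by) {
  stopifnot("n" %in% names(ehr_counts), "n" %in% names(census_counts))
  out <- dplyr::full_join(
    ehr_counts |> dplyr::rename(ehr_n = "n"),
    census_counts |> dplyr::rename(census_n = "n"),
    by = by
  ) |>
    dplyr::mutate(
      ehr_n = dplyr::coalesce(.data$ehr_n, 0),
      census_n = dplyr::coalesce(.data$census_n, 0),
      undefined = .data$census_n == 0,
      ratio = ifelse(.data$undefined, NA_real_, .data$ehr_n / .data$census_n),
      ratio_display = round_half_up(.data$ratio, 2)
    )
  out[do.call(order, out[by]), ]
}

#' Coverage of a reference population
#'
#' The EHR patient count as a percentage of the census estimate
#' (`100 * ehr_total / census_total`). Display convention is one decimal,
#' half-up ([round_half_up()]); the unrounded value is returned.
#'
#' @param ehr_total EHR person count.
#' @param census_total Census population count (> 0).
#' @return Unrounded percentage.
#' @export
coverage_percent <- function(ehr_total, census_total) {
  percent_of(ehr_total, census_total)
}

#' Median and IQR of per-county coverage ratios
#'
#' @param ratios Numeric vector of per-county EHR-to-census ratios.
#' @return Tibble with `n_counties`, `median`, `q25`, `q75` (quantile
#'   type 7, linear interpolation).
#' @export
county_ratio_summary <- function(ratios) {
  stopifnot(length(ratios) >= 1)
  q <- stats::quantile(ratios, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n_counties = length(ratios), median = q[2], q25 = q[1], q75 = q[3]
  )
}

#' Relative difference of an estimate from a reference
#'
#' `(estimate - reference) / reference`, the agreement metric behind the
#' "within X%" concordance bands. Undefined (NA) where the reference is
#' not positive.
#'
#' @param estimate,reference Numeric vectors on the same scale.
#' @return Numeric vector of relative differences.
#' @export
relative_difference <- function(estimate, reference) {
  ifelse(reference > 0, (estimate - reference) / reference, NA_real_)
}

#' Tract-level concordance and Bland-Altman agreement
#'
#' Compares EHR-derived and reference (model-based) tract prevalence
#' tables on their common tracts: per-tract relative difference with
#' within-band indicators (inclusive at the boundary, reference in the
#' denominator), and Bland-Altman components (difference EHR minus
#' reference, mean-of-pair, mean difference, limits of agreement at
#' mean +/- 1.96 SD). Tracts present in only one source, and tracts with
#' a zero reference prevalence, are excluded from concordance and listed
#' in an exclusions table.
#'
#' @param ehr Tibble with `tract_id` and `prevalence_pct` for the EHR
#'   source.
#' @param reference Same shape for the reference source.
#' @param bands Relative-difference bands (default 10% and 25%).
#' @return An object of class `tractprev_concordance`: a list with
#'   per-tract `tracts`, one-row `summary`, `bands`, and `exclusions`.
#'   Use [tidy()][generics::tidy], [glance()][generics::glance], and
#'   [autoplot()][ggplot2::autoplot].
#' @export
concordance <- function(ehr, reference, bands = c(0.10, 0.25)) {
  bands <- sort(bands)
  common <- dplyr::inner_join(
    ehr |> dplyr::select("tract_id", ehr_pct = "prevalence_pct"),
    reference |> dplyr::select("tract_id", ref_pct = "prevalence_pct"),
    by = "tract_id"
  )
  exclusions <- dplyr::bind_rows(
    ehr |>
      dplyr::anti_join(reference, by = "tract_id") |>
      dplyr::transmute(.data$tract_id, reason = "missing_in_reference"),
    reference |>
      dplyr::anti_join(ehr, by = "tract_id") |>
      dplyr::transmute(.data$tract_id, reason = "missing_in_ehr"),
    common |>
      dplyr::filter(.data$ref_pct <= 0) |>
      dplyr::transmute(.data$tract_id, reason = "zero_reference_prevalence")
  )
  tracts <- common |>
    dplyr::filter(.data$ref_pct > 0) |>
    dplyr::mutate(
      rel_diff = relative_difference(.data$ehr_pct, .data$ref_pct),
      difference = .data$ehr_pct - .data$ref_pct,
      mean_pair = (.data$ehr_pct + .data$ref_pct) / 2
    )
  for (b in bands) {
    tracts[[sprintf("within_%gpct", 100 * b)]] <- abs(tracts$rel_diff) <= b
  }

  n <- nrow(tracts)
  sd_diff <- if (n > 1) stats::sd(tracts$difference) else 0
  mean_diff <- if (n > 0) mean(tracts$difference) else NA_real_
  summary <- tibble::tibble(
    n_tracts = n,
    mean_difference = mean_diff,
    sd_difference = sd_diff,
    loa_low = mean_diff - 1.96 * sd_diff,
    loa_high = mean_diff + 1.96 * sd_diff
  )
  for (b in bands) {
    col <- sprintf("within_%gpct", 100 * b)
    summary[[paste0("n_", col)]] <- sum(tracts[[col]])
    summary[[paste0("share_", col)]] <-
      if (n > 0) percent_of(sum(tracts[[col]]), n) else NA_real_
  }

  structure(
    list(tracts = tracts, summary = summary, bands = bands,
         exclusions = exclusions),
    class = "tractprev_concordance"
  )
}

#' @export
print.tractprev_concordance <- function(x, ...) {
  s <- x$summary
  cat("<tractprev_concordance> ", s$n_tracts, " tracts\n", sep = "")
  for (b in x$bands) {
    col <- sprintf("within_%gpct", 100 * b)
    cat(sprintf(
      "  within %g%%: %d/%d (%s%%)\n", 100 * b,
      s[[paste0("n_", col)]], s$n_tracts,
      format(round_half_up(s[[paste0("share_", col)]], 1), nsmall = 1)
    ))
  }
  cat(sprintf(
    "  Bland-Altman: mean difference %.3f, limits (%.3f, %.3f)\n",
    s$mean_difference, s$loa_low, s$loa_high
  ))
  if (nrow(x$exclusions) > 0) {
    cat("  excluded tracts:", nrow(x$exclusions), "\n")
  }
  invisible(x)
}

#' @rdname concordance
#' @param x A `tractprev_concordance` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tractprev_concordance <- function(x, ...) x$tracts

#' @rdname concordance
#' @exportS3Method generics::glance
glance.tractprev_concordance <- function(x, ...) x$summary
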