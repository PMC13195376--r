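#' Quartile categories for a continuous social vulnerability index
#'
#' Cuts continuous SVI values at the within-dataset 25th/50th/75th
#' percentiles (quantile type 7, linear interpolation). Quartile 1 is the
#' lowest vulnerability; values tied with a boundary fall in the lower
#' quartile (intervals are closed on the right). Constant input
#' degenerates to a single quartile with a warning.
#'
#' @param x Numeric vector of continuous SVI values (>= 4 tracts).
#' @return Factor with levels `1:4`.
#' @export
svi_quartiles <- function(x) {
  stopifnot(length(x) >= 4, !anyNA(x))
  breaks <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1),
    type = 7, names = FALSE
  )
  if (anyDuplicated(breaks)) {
    if (breaks[1] == breaks[5]) {
      warning("constant SVI: all tracts assigned quartile 1", call. = FALSE)
      return(factor(rep(1L, length(x)), levels = 1:4))
    }
    # heavy ties: collapse duplicated boundaries; a bin takes the quartile
    # number of its upper edge, so boundary ties still go to the lower
    # quartile
    ub <- unique(breaks)
    q <- cut(x, ub, labels = FALSE, include.lowest = TRUE, right = TRUE)
    lab <- match(ub[-1], breaks) - 1L
    warning("tied SVI quantile boundaries: fewer than 4 distinct quartiles",
      call. = FALSE
    )
    return(factor(lab[q], levels = 1:4))
  }
  factor(
    cut(x, breaks, labels = FALSE, include.lowest = TRUE, right = TRUE),
    levels = 1:4
  )
}

model_terms <- c(
  "pct_over_65", "pct_black", "pct_aian", "pct_asian_hpi",
  "svi_quartile", "urbanicity", "pct_below_poverty", "pct_hs_or_ged"
)

#' Ordinary least squares model of tract prevalence on tract covariates
#'
#' Fits `prevalence_pct ~ pct_over_65 + pct_black + pct_aian +
#' pct_asian_hpi + svi_quartile + urbanicity + pct_below_poverty +
#' pct_hs_or_ged` by OLS, with dummy coding against reference levels
#' SVI quartile 1 and urban. Percentage predictors are on the 0-100 scale,
#' so coefficients are percentage points of prevalence per percentage
#' point of the covariate. Inference is normal-theory (non-robust): the
#' model assumes independence across census tracts, which understates
#' uncertainty when tracts are spatially correlated.
#'
#' @param estimates Tract estimate tibble with `tract_id` and
#'   `prevalence_pct` (e.g. from [tract_prevalence()] or a model-based
#'   source), optionally pre-filtered by `source`/`condition` columns.
#' @param covariates Tract covariate tibble with `tract_id`, the four
#'   percentage covariates, `svi_quartile` (1-4) and `urbanicity`
#'   (urban/exurban/rural/small_town).
#' @param source,condition Optional filters applied to matching columns of
#'   `estimates`, recorded on the result.
#' @return Object of class `tract_model` wrapping the `lm` fit; supports
#'   [tidy()][generics::tidy] (estimates, 95% CIs, p-values),
#'   [glance()][generics::glance] (R^2 etc.) and
#'   [autoplot()][ggplot2::autoplot].
#' @export
fit_prevalence_model <- function(estimates, covariates,
                                 source = NULL, condition = NULL) {
  if (!is.null(source) && "source" %in% names(estimates)) {
    estimates <- estimates |> dplyr::filter(.data$source == !!source)
  }
  if (!is.null(condition) && "condition" %in% names(estimates)) {
    estimates <- estimates |> dplyr::filter(.data$condition == !!condition)
  }
  dat <- estimates |>
    dplyr::select("tract_id", "prevalence_pct") |>
    dplyr::inner_join(
      covariates |> dplyr::select("tract_id", dplyr::all_of(model_terms)),
      by = "tract_id"
    ) |>
    dplyr::mutate(
      svi_quartile = factor(.data$svi_quartile, levels = 1:4),
      urbanicity = factor(.data$urbanicity,
        levels = c("urban", "exurban", "rural", "small_town")
      )
    ) |>
    stats::na.omit()

  fit <- stats::lm(
    stats::reformulate(model_terms, response = "prevalence_pct"),
    data = dat
  )
  mm <- stats::model.matrix(fit)
  if (fit$rank < ncol(mm)) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop(
      "rank-deficient design: collinear term(s) ",
      paste(aliased, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(dat) < ncol(mm) + 2) {
    stop(
      "need at least ", ncol(mm) + 2, " complete tracts, got ", nrow(dat),
      call. = FALSE
    )
  }
  structure(
    list(
      fit = fit, data = dat, n = nrow(dat),
      source = source, condition = condition
    ),
    class = "tract_model"
  )
}

#' @export
print.tract_model <- function(x, ...) {
  cat("<tract_model>",
    if (!is.null(x$condition)) x$condition, if (!is.null(x$source)) x$source,
    sprintf("(%d tracts, R^2 = %.3f)\n", x$n, summary(x$fit)$r.squared)
  )
  print(tidy.tract_model(x))
  invisible(x)
}

#' @rdname fit_prevalence_model
#' @param x A `tract_model` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tract_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = 0.95)
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    conf.low = ci[, 1],
    conf.high = ci[, 2],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname fit_prevalence_model
#' @exportS3Method generics::glance
glance.tract_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    n = x$n
  )
}
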