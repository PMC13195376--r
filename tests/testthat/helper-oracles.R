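# Brute-force oracles, written independently of the package internals:
# plain loops over event rows, evaluating every (window, disjunct)
# combination directly.

oracle_hypertension <- function(conditions, bp, index_year) {
  dx <- FALSE
  for (i in seq_len(nrow(conditions))) {
    yr <- as.integer(format(conditions$condition_date[i], "%Y"))
    if (conditions$condition[i] == "hypertension" &&
      yr >= index_year - 4 && yr <= index_year) {
      dx <- TRUE
    }
  }
  qual_days <- character(0)
  for (i in seq_len(nrow(bp))) {
    yr <- as.integer(format(bp$measurement_date[i], "%Y"))
    sbp_hi <- !is.na(bp$sbp[i]) && bp$sbp[i] >= 140
    dbp_hi <- !is.na(bp$dbp[i]) && bp$dbp[i] >= 90
    if (isTRUE(bp$outpatient[i]) && yr >= index_year - 2 && yr <= index_year &&
      (sbp_hi || dbp_hi)) {
      qual_days <- union(qual_days, format(bp$measurement_date[i]))
    }
  }
  dx || length(qual_days) >= 2
}

oracle_diabetes <- function(conditions, a1c, index_year) {
  dx <- FALSE
  for (i in seq_len(nrow(conditions))) {
    yr <- as.integer(format(conditions$condition_date[i], "%Y"))
    if (conditions$condition[i] == "diabetes" &&
      yr >= index_year - 4 && yr <= index_year) {
      dx <- TRUE
    }
  }
  lab <- 0L
  for (i in seq_len(nrow(a1c))) {
    yr <- as.integer(format(a1c$measurement_date[i], "%Y"))
    if (!is.na(a1c$a1c[i]) && a1c$a1c[i] >= 6.5 &&
      yr >= index_year - 2 && yr <= index_year) {
      lab <- lab + 1L
    }
  }
  dx || lab >= 1L
}

# Sort-based type-7 quantile: h = (n-1)p + 1, linear interpolation.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, n)] - s[lo])
}

# Random event history for one person: up to ~50 events straddling every
# window boundary, threshold, and the outpatient flag.
random_history <- function(index_year = 2020) {
  rand_dates <- function(k) {
    as.Date(sprintf("%d-12-31", index_year)) - sample(0:(365 * 7), k, TRUE)
  }
  n_dx <- sample(0:4, 1)
  n_bp <- sample(0:30, 1)
  n_a1c <- sample(0:10, 1)
  list(
    conditions = tibble::tibble(
      identity_hash = "h1",
      condition = sample(c("hypertension", "diabetes"), n_dx, TRUE),
      condition_date = rand_dates(n_dx)
    ),
    bp = tibble::tibble(
      identity_hash = "h1",
      measurement_date = sample(rand_dates(6), n_bp, TRUE),
      sbp = sample(c(NA, 120, 139.9, 140, 145, 180), n_bp, TRUE),
      dbp = sample(c(NA, 70, 89.9, 90, 95), n_bp, TRUE),
      outpatient = sample(c(TRUE, TRUE, FALSE), n_bp, TRUE)
    ),
    a1c = tibble::tibble(
      identity_hash = "h1",
      measurement_date = rand_dates(n_a1c),
      a1c = sample(c(NA, 5.4, 6.49, 6.5, 8.1), n_a1c, TRUE)
    )
  )
}

# Small, fast default configuration for pipeline tests.
small_config <- function(seed = 42, ...) {
  sim_config(seed = seed, n_persons = 3000, n_tracts = 25, ...)
}

# A fully deterministic care-seeking table: everyone seeks care.
always_care <- function(mix = default_demographic_mix()) {
  dplyr::mutate(
    dplyr::select(mix, -"prop"),
    care_prob = 1
  )
}

# Synthetic tract covariate table with no generator involvement, for the
# model-fitting tests.
make_covariates <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    tract_id = sprintf("X%04d", seq_len(n)),
    pct_over_65 = runif(n, 5, 35),
    pct_black = runif(n, 0, 40),
    pct_aian = runif(n, 0, 10),
    pct_asian_hpi = runif(n, 0, 20),
    svi_quartile = factor(sample(1:4, n, TRUE), levels = 1:4),
    urbanicity = factor(
      sample(c("urban", "exurban", "rural", "small_town"), n, TRUE),
      levels = c("urban", "exurban", "rural", "small_town")
    ),
    pct_below_poverty = runif(n, 0, 40),
    pct_hs_or_ged = runif(n, 60, 100)
  ))
}

# Linear outcome from known coefficients on the make_covariates() design.
linear_outcome <- function(cov, beta) {
  beta["intercept"] +
    beta["pct_over_65"] * cov$pct_over_65 +
    beta["pct_black"] * cov$pct_black +
    beta["pct_aian"] * cov$pct_aian +
    beta["pct_asian_hpi"] * cov$pct_asian_hpi +
    beta["svi2"] * (cov$svi_quartile == 2) +
    beta["svi3"] * (cov$svi_quartile == 3) +
    beta["svi4"] * (cov$svi_quartile == 4) +
    beta["exurban"] * (cov$urbanicity == "exurban") +
    beta["rural"] * (cov$urbanicity == "rural") +
    beta["small_town"] * (cov$urbanicity == "small_town") +
    beta["pct_below_poverty"] * cov$pct_below_poverty +
    beta["pct_hs_or_ged"] * cov$pct_hs_or_ged
}

test_beta <- c(
  intercept = 30, pct_over_65 = 0.5, pct_black = -0.1, pct_aian = 0.08,
  pct_asian_hpi = -0.05, svi2 = 1.5, svi3 = 2.1, svi4 = 2.6,
  exurban = 4, rural = 4.2, small_town = 5.9,
  pct_below_poverty = -0.05, pct_hs_or_ged = -0.2
)
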