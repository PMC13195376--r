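#' Round half away from zero
#'
#' Display rounding for ratios and percentages. Base [round()] rounds half to
#' even; published surveillance tables round half up, so 0.975 must display
#' as 0.98, not 0.97. Machine outputs always retain the unrounded value; this
#' helper is only for display columns.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.975, 92.35), c(2, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small eps guards against values like 0.97499999999 produced by division
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a reference total
#'
#' `100 * n / total`, the arithmetic behind coverage percentages and
#' within-band concordance shares.
#'
#' @param n Numerator count.
#' @param total Reference total; must be positive.
#' @return Unrounded percentage.
#' @export
percent_of <- function(n, total) {
  stopifnot(all(total > 0))
  100 * n / total
}

#' Prevalence on the 0-100 scale
#'
#' @param numerator Case count (possibly fractional after crosswalk
#'   allocation).
#' @param denominator Population count; must be positive.
#' @return Prevalence percentage.
#' @export
prevalence_pct <- function(numerator, denominator) {
  stopifnot(all(denominator > 0))
  100 * numerator / denominator
}

#' Salted 32-bit FNV-1a hash of strings
#'
#' Stands in for the privacy-preserving hashed identifiers used in
#' multi-system record linkage: the same (name, birth date, salt) triple
#' always maps to the same opaque token, and the token is stable across
#' systems. This is deterministic plumbing for linkage semantics, not a
#' cryptographic primitive.
#'
#' @param x Character vector to hash.
#' @param salt Salt string prepended to every element.
#' @return Character vector of 8-digit lowercase hex tokens.
#' @export
fnv1a_hash <- function(x, salt = "") {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  x <- paste0(salt, x)
  ints <- lapply(x, utf8ToInt)
  n <- length(x)
  len <- lengths(ints)
  maxlen <- max(len, 1L)
  m <- matrix(NA_integer_, nrow = n, ncol = maxlen)
  if (sum(len) > 0) {
    m[cbind(rep(seq_len(n), len), sequence(len))] <- unlist(ints)
  }
  h <- rep(2166136261, n)
  prime <- 16777619
  for (j in seq_len(maxlen)) {
    v <- m[, j]
    a <- !is.na(v)
    if (!any(a)) break
    lo8 <- h[a] %% 256
    h[a] <- h[a] - lo8 + bitwXor(as.integer(lo8), v[a])
    # 32-bit modular multiply in doubles, split to stay exact
    hi <- h[a] %/% 65536
    lo <- h[a] %% 65536
    h[a] <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Deterministic uniform deviate from a string key
#'
#' Maps a key (e.g. an identity hash plus a seed) to a value in `[0, 1)`
#' without touching R's RNG stream; used for order-invariant per-person
#' sampling.
#'
#' @param key Character vector.
#' @return Numeric vector in `[0, 1)`.
#' @keywords internal
hash_unit <- function(key) {
  h <- fnv1a_hash(key)
  (strtoi(substr(h, 1, 4), 16L) * 65536 + strtoi(substr(h, 5, 8), 16L) + 0.5) /
    4294967296
}

#' Age in completed years on a reference date
#'
#' @param birth_date,ref_date Date vectors.
#' @return Integer vector of completed years.
#' @keywords internal
age_on <- function(birth_date, ref_date) {
  as.integer(floor(lubridate::interval(birth_date, ref_date) /
    lubridate::years(1)))
}

#' Age-group label used throughout the package
#' @keywords internal
age_group_of <- function(age) {
  cut(age,
    breaks = c(-Inf, 17, 44, 64, Inf),
    labels = c("0-17", "18-44", "45-64", "65+")
  ) |> as.character()
}

dec31 <- function(year) as.Date(sprintf("%d-12-31", year))
jan1 <- function(year) as.Date(sprintf("%d-01-01", year))
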