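#' Normalize a free-text term
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace to
#' a single space, and uppercases. Used for drug names, preferred terms and
#' vocabulary keys so that cosmetic spelling variants ("  Nourianz ",
#' "Freezing  phenomenon") collapse onto one key.
#'
#' @param raw Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_term(c("  Nourianz ", "Freezing  phenomenon"))
#' @export
normalize_term <- function(raw) {
  toupper(stringr::str_squish(as.character(raw)))
}

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (0.125 -> 0.13 at 2 digits),
#' the convention used for all printed percentages and table statistics.
#' Base `round()` rounds half to even, which disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count, printed-table convention
#'
#' `100 * count / total`, rounded half-up to two decimals — the format used in
#' descriptive report-characteristics tables (e.g. 388 of 3633 -> 10.68).
#'
#' @param count Numerator count(s).
#' @param total Denominator count (must be > 0).
#' @return Numeric vector of percentages with two-decimal precision.
#' @examples
#' percent(388, 3633)
#' @export
percent <- function(count, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    abort("`total` must be a single positive count.", class = "faersignal_error_denominator")
  }
  round_half_up(100 * count / total, 2)
}

# Parse FAERS-style numeric date strings. Full dates are 8-digit YYYYMMDD.
# When partial = TRUE, 6-digit YYYYMM and 4-digit YYYY are padded to the first
# day of the period (used for therapy start / event onset dates, which FAERS
# often truncates). Invalid or non-date input -> NA.
parse_faers_date <- function(x, partial = FALSE) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x) | x == ""] <- NA_character_
  digits <- !is.na(x) & grepl("^[0-9]+$", x)
  out <- rep(as.Date(NA), length(x))
  full <- digits & nchar(x) == 8
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  if (partial) {
    ym <- digits & nchar(x) == 6
    out[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
    y <- digits & nchar(x) == 4
    out[y] <- as.Date(paste0(x[y], "0101"), format = "%Y%m%d")
  }
  out
}

# Deterministic ordering key for case/report identifiers. FAERS PRIMARYID /
# CASEID are digit strings in practice, and "largest PRIMARYID" means numeric
# order; but the ids are contractually opaque, so when any id in the vector is
# non-numeric the whole vector falls back to lexicographic (C-locale) order.
# Returns a vector that sorts in the intended order under `order()`/`arrange()`.
id_order_key <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) && all(grepl("^[0-9]+$", ids[!is.na(ids)]))) {
    # pad to equal width so character sort == numeric sort (ids can exceed
    # double precision in principle)
    w <- max(nchar(ids), 0L)
    formatC(ids, width = w, flag = "0")
  } else {
    ids
  }
}

issue_warning <- function(msg, class) {
  warn(msg, class = c(class, "faersignal_warning"))
}
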