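# Descriptive characteristics of the target-drug cohort: sex, age bins,
# reporter occupation, country, report year, serious outcomes, and
# time-to-onset bins, each with a percentage of the total report count.

#' Convert a FAERS age to years
#'
#' FAERS stores ages with a unit code. Conversion factors: `YR` identity,
#' `DEC` decades (x10), `MON` months (/12), `WK` weeks (/52.18), `DY` days
#' (/365.25), `HR` hours (/8766). Unknown units yield missing with a warning.
#'
#' @param age Numeric age values (>= 0).
#' @param unit Age unit codes.
#' @return Age in years (double), `NA` where not interpretable.
#' @examples
#' age_in_years(900, "MON")   # 75
#' @export
age_in_years <- function(age, unit) {
  factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)
  unit <- toupper(as.character(unit))
  unknown <- !is.na(age) & !is.na(unit) & !unit %in% names(factor)
  if (any(unknown)) {
    issue_warning(
      paste0("Unknown age unit(s): ",
             paste(unique(unit[unknown]), collapse = ", "),
             "; ages treated as missing."),
      "faersignal_warning_age_unit"
    )
  }
  f <- unname(factor[unit])
  out <- as.numeric(age) * f
  out[unknown] <- NA_real_
  out
}

age_bin_labels <- c("<18", "\u226518,<45", "\u226545,<65", "\u226565,<75",
                    "\u226575", "Unknown")

#' Bin an age in years into the reporting age groups
#'
#' Half-open bins `[0,18)`, `[18,45)`, `[45,65)`, `[65,75)`, `[75,Inf)`;
#' missing or negative ages go to `"Unknown"` (negative with a warning).
#'
#' @param years Numeric ages in years (may contain `NA`).
#' @return Character bin labels.
#' @export
bin_age <- function(years) {
  neg <- !is.na(years) & years < 0
  if (any(neg)) {
    issue_warning("Negative age(s) treated as Unknown.",
                  "faersignal_warning_negative_age")
  }
  years[neg] <- NA_real_
  dplyr::case_when(
    is.na(years) ~ "Unknown",
    years < 18 ~ age_bin_labels[1],
    years < 45 ~ age_bin_labels[2],
    years < 65 ~ age_bin_labels[3],
    years < 75 ~ age_bin_labels[4],
    TRUE ~ age_bin_labels[5]
  )
}

onset_bin_labels <- c("0-7", "7-28", "28-60", "\u226560", "Unknown")

#' Days from therapy start to event onset
#'
#' Whole days `event_dt - start_dt` when both dates are present and the gap
#' is non-negative; negative gaps (likely data errors) and missing dates are
#' returned as `NA` and later reported as `"Unknown"`.
#'
#' @param event_dt,start_dt `Date` vectors.
#' @return Integer days or `NA`.
#' @export
time_to_onset_days <- function(event_dt, start_dt) {
  d <- as.integer(as.Date(event_dt) - as.Date(start_dt))
  d[!is.na(d) & d < 0] <- NA_integer_
  d
}

#' Bin time-to-onset days
#'
#' Half-open, lower-inclusive bins `[0,7)`, `[7,28)`, `[28,60)`, `[60,Inf)`;
#' `NA` maps to `"Unknown"`.
#'
#' @param days Integer day counts (may contain `NA`).
#' @return Character bin labels.
#' @export
bin_onset <- function(days) {
  dplyr::case_when(
    is.na(days) ~ "Unknown",
    days < 7 ~ onset_bin_labels[1],
    days < 28 ~ onset_bin_labels[2],
    days < 60 ~ onset_bin_labels[3],
    TRUE ~ onset_bin_labels[4]
  )
}

reporter_labels <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                     HP = "Other health professionals",
                     OT = "Other health professionals")

outcome_labels <- c(DE = "Death", DS = "Disability",
                    HO = "Hospitalization\u2014initial or prolonged",
                    LT = "Life-threatening", CA = "Congenital anomaly",
                    RI = "Required intervention", OT = "Other serious")

country_labels <- c(US = "United States", JP = "Japan", DE = "Germany",
                    GB = "United Kingdom", CA = "Canada", FR = "France",
                    CN = "China", COUNTRY_NOT_SPECIFIED = "Not specified")

#' Assemble a per-report cohort table
#'
#' Joins the kept DEMO rows of the target cohort with their serious-outcome
#' codes and the earliest therapy start date of the target drug, yielding one
#' row per report with everything [summarize_reports()] needs. Onset uses the
#' DEMO event date and the earliest `start_dt` among THER rows linked (via
#' `dsg_drug_seq` = `drug_seq`) to a target-drug DRUG row; when the drug-seq
#' link is unavailable the earliest start date in the report is used.
#'
#' @param demo Kept DEMO rows of the cohort (already filtered to target
#'   reports).
#' @param outc OUTC rows (optional).
#' @param ther THER rows (optional).
#' @param drug DRUG rows (optional, for the target-drug start-date link).
#' @param target_names Normalized target drug names (used with `drug`).
#' @return Tibble, one row per report, with `outcomes` (list of codes) and
#'   `onset_days` columns added.
#' @export
assemble_cohort <- function(demo, outc = NULL, ther = NULL, drug = NULL,
                            target_names = NULL) {
  cohort <- as_tibble(demo)
  if (!is.null(outc) && nrow(as_tibble(outc))) {
    oc <- as_tibble(outc) %>%
      distinct(.data$primaryid, .data$outc_cod) %>%
      group_by(.data$primaryid) %>%
      summarise(outcomes = list(.data$outc_cod), .groups = "drop")
    cohort <- left_join(cohort, oc, by = "primaryid")
  } else {
    cohort$outcomes <- vector("list", nrow(cohort))
  }
  cohort$outcomes <- purrr::map(cohort$outcomes, ~ .x %||% character())

  starts <- NULL
  if (!is.null(ther) && nrow(as_tibble(ther))) {
    th <- as_tibble(ther)
    if (!is.null(drug) && !is.null(target_names) &&
        "drug_seq" %in% names(drug) && any(!is.na(drug$drug_seq))) {
      tgt <- as_tibble(drug) %>%
        filter(normalize_term(.data$drugname) %in% target_names |
                 normalize_term(.data$prod_ai) %in% target_names) %>%
        select("primaryid", "drug_seq")
      th <- dplyr::inner_join(th, tgt,
                              by = c("primaryid", dsg_drug_seq = "drug_seq"))
    }
    starts <- th %>%
      filter(!is.na(.data$start_dt)) %>%
      group_by(.data$primaryid) %>%
      summarise(start_dt = min(.data$start_dt), .groups = "drop")
  }
  if (!is.null(starts) && nrow(starts)) {
    cohort <- left_join(cohort, starts, by = "primaryid")
  } else {
    cohort$start_dt <- as.Date(NA)
  }
  cohort$onset_days <- time_to_onset_days(cohort$event_dt, cohort$start_dt)
  cohort
}

section_tbl <- function(section, labels, counts, total) {
  tibble(section = section, label = labels,
         count = as.integer(counts), percent = percent(counts, total))
}

count_levels <- function(x, levels) {
  x[is.na(x)] <- "Unknown"
  tab <- table(factor(x, levels = levels))
  as.integer(tab)
}

#' Summarize a target-drug cohort
#'
#' Produces the descriptive report-characteristics table: counts and
#' percentages by sex, age group, reporter occupation, occurrence country,
#' report year, serious outcome, and time-to-onset bin. Sex, age, reporter,
#' year and onset sections partition the cohort (missing values under
#' `"Unknown"`), so their counts sum to the total; a report can carry several
#' outcome codes and the country section lists observed countries, so those
#' two sections need not partition. All percentages use the total report
#' count as denominator, rounded half-up to two decimals.
#'
#' @param cohort Per-report tibble from [assemble_cohort()].
#' @return A `descriptive_summary` tibble with columns `section`, `label`,
#'   `count`, `percent` and attribute `total_reports`.
#' @export
summarize_reports <- function(cohort) {
  cohort <- as_tibble(cohort)
  total <- nrow(cohort)
  if (!total) {
    abort("Cannot summarize an empty cohort.",
          class = "faersignal_error_denominator")
  }

  sex_lv <- c("Female", "Male", "Unknown")
  sex <- dplyr::recode(cohort$sex, F = "Female", M = "Male",
                       .missing = "Unknown")
  out <- list(section_tbl("sex", sex_lv, count_levels(sex, sex_lv), total))

  years <- age_in_years(cohort$age, cohort$age_unit)
  out <- c(out, list(section_tbl(
    "age", age_bin_labels, count_levels(bin_age(years), age_bin_labels), total
  )))

  rep_lv <- c("Physician", "Pharmacist", "Consumer",
              "Other health professionals", "Unknown")
  reporter <- unname(reporter_labels[cohort$occp_cod])
  out <- c(out, list(section_tbl(
    "reporter", rep_lv, count_levels(reporter, rep_lv), total
  )))

  country <- cohort$occr_country
  country[is.na(country)] <- "COUNTRY_NOT_SPECIFIED"
  country <- dplyr::coalesce(unname(country_labels[country]), country)
  ctab <- sort(table(country), decreasing = TRUE)
  out <- c(out, list(section_tbl(
    "country", names(ctab), as.integer(ctab), total
  )))

  ytab <- table(factor(cohort$report_year))
  out <- c(out, list(section_tbl("year", names(ytab), as.integer(ytab), total)))

  oc <- unlist(purrr::map(cohort$outcomes, unique))
  otab <- table(factor(oc, levels = names(outcome_labels)))
  out <- c(out, list(section_tbl(
    "outcomes", unname(outcome_labels), as.integer(otab), total
  )))

  out <- c(out, list(section_tbl(
    "onset", onset_bin_labels,
    count_levels(bin_onset(cohort$onset_days), onset_bin_labels), total
  )))

  res <- bind_rows(out)
  attr(res, "total_reports") <- total
  class(res) <- c("descriptive_summary", class(res))
  res
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("Descriptive summary of", attr(x, "total_reports"), "reports\n")
  NextMethod()
}
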