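# Readers and writers for the FAERS quarterly ASCII dialect: "$"-delimited
# text with one header row and no quoting. Embedded "$" inside free-text
# fields is not representable in this dialect and is not supported.

faers_schemas <- list(
  demo = list(
    mandatory = c("primaryid", "caseid", "fda_dt"),
    optional  = c("event_dt", "age", "age_cod", "age_unit", "sex", "gndr_cod",
                  "occp_cod", "occr_country")
  ),
  drug = list(
    mandatory = c("primaryid", "drugname", "role_cod"),
    optional  = c("drug_seq", "prod_ai")
  ),
  reac = list(
    mandatory = c("primaryid", "pt"),
    optional  = character()
  ),
  outc = list(
    mandatory = c("primaryid", "outc_cod"),
    optional  = character()
  ),
  ther = list(
    mandatory = c("primaryid", "dsg_drug_seq"),
    optional  = c("start_dt")
  )
)

role_codes <- c("PS", "SS", "C", "I")
outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
age_unit_codes <- c("YR", "DEC", "MON", "WK", "DY", "HR")

blank_to_na <- function(x) {
  x <- stringr::str_trim(x)
  dplyr::if_else(is.na(x) | x == "", NA_character_, x)
}

#' Read a FAERS-style quarterly table
#'
#' Parses one "$"-delimited FAERS quarterly-extract table (DEMO, DRUG, REAC,
#' OUTC or THER) into a typed tibble. Column names are matched
#' case-insensitively (FAERS header case varies across quarters); columns not
#' in the schema are ignored, and absent optional columns come back as
#' all-missing. Rows whose mandatory fields fail validation (empty ids, an
#' FDA receipt date that is not a valid 8-digit `YYYYMMDD` date, a drug role
#' or outcome code outside the FAERS code set, a blank preferred term) are
#' dropped with a warning; the number of dropped rows and their 1-based data
#' line numbers are attached as attributes `skipped` and `skipped_lines`.
#'
#' Dates: `fda_dt` must be a full valid `YYYYMMDD` date because it drives
#' deduplication order. `event_dt` and `start_dt` may be partial (`YYYYMM` or
#' `YYYY`), padded to the first day of the period; unparseable values become
#' missing. A `DEMO` `age` without a usable `age_cod`/`age_unit` is treated
#' as missing.
#'
#' @param path Path to the table file.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`.
#' @return A tibble, one row per retained data line:
#'   * `demo`: `primaryid`, `caseid`, `fda_dt` (Date), `event_dt` (Date),
#'     `age` (double), `age_unit`, `sex`, `occp_cod`, `occr_country`,
#'     `report_year` (int).
#'   * `drug`: `primaryid`, `drug_seq` (int), `drugname`, `prod_ai`,
#'     `role_cod`.
#'   * `reac`: `primaryid`, `pt`.
#'   * `outc`: `primaryid`, `outc_cod`.
#'   * `ther`: `primaryid`, `dsg_drug_seq` (int), `start_dt` (Date).
#' @export
read_faers_table <- function(path, kind = c("demo", "drug", "reac", "outc", "ther")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "faersignal_error_io")
  }
  schema <- faers_schemas[[kind]]
  raw <- readr::read_delim(
    path, delim = "$", quote = "", col_types = readr::cols(.default = "c"),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE
  )
  names(raw) <- tolower(stringr::str_trim(names(raw)))
  missing_cols <- setdiff(schema$mandatory, names(raw))
  if (length(missing_cols)) {
    abort(
      paste0("Table '", path, "' (kind ", kind, ") lacks mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "faersignal_error_format"
    )
  }
  for (col in schema$optional) if (!col %in% names(raw)) raw[[col]] <- NA_character_
  raw <- raw[union(schema$mandatory, schema$optional)]
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(), blank_to_na))

  out <- switch(kind,
    demo = parse_demo(raw),
    drug = parse_drug(raw),
    reac = parse_reac(raw),
    outc = parse_outc(raw),
    ther = parse_ther(raw)
  )
  bad <- out$bad
  res <- out$tbl[!bad, , drop = FALSE]
  attr(res, "skipped") <- sum(bad)
  attr(res, "skipped_lines") <- which(bad)
  if (any(bad)) {
    issue_warning(
      paste0("read_faers_table(", kind, "): skipped ", sum(bad),
             " malformed row(s) at data line(s) ",
             paste(head(which(bad), 10), collapse = ", "),
             if (sum(bad) > 10) ", ..." else "", " in ", path),
      "faersignal_warning_skipped_rows"
    )
  }
  res
}

parse_demo <- function(raw) {
  fda <- parse_faers_date(raw$fda_dt, partial = FALSE)
  # accept either FAERS age_cod or the generic age_unit header
  unit <- toupper(dplyr::coalesce(raw$age_cod, raw$age_unit))
  unit[!unit %in% age_unit_codes] <- NA_character_
  age <- suppressWarnings(as.numeric(raw$age))
  age[is.na(unit)] <- NA_real_      # age without a unit is uninterpretable
  unit[is.na(age)] <- NA_character_
  sex <- toupper(dplyr::coalesce(raw$sex, raw$gndr_cod))
  sex[!sex %in% c("F", "M")] <- NA_character_
  tbl <- tibble(
    primaryid = raw$primaryid,
    caseid = raw$caseid,
    fda_dt = fda,
    event_dt = parse_faers_date(raw$event_dt, partial = TRUE),
    age = age,
    age_unit = unit,
    sex = sex,
    occp_cod = toupper(raw$occp_cod),
    occr_country = toupper(raw$occr_country),
    report_year = as.integer(format(fda, "%Y"))
  )
  bad <- is.na(tbl$primaryid) | is.na(tbl$caseid) | is.na(tbl$fda_dt)
  list(tbl = tbl, bad = bad)
}

parse_drug <- function(raw) {
  tbl <- tibble(
    primaryid = raw$primaryid,
    drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
    drugname = raw$drugname,
    prod_ai = raw$prod_ai,
    role_cod = toupper(raw$role_cod)
  )
  bad <- is.na(tbl$primaryid) | is.na(tbl$drugname) | !tbl$role_cod %in% role_codes
  list(tbl = tbl, bad = bad)
}

parse_reac <- function(raw) {
  tbl <- tibble(primaryid = raw$primaryid, pt = raw$pt)
  bad <- is.na(tbl$primaryid) | is.na(tbl$pt)
  list(tbl = tbl, bad = bad)
}

parse_outc <- function(raw) {
  tbl <- tibble(primaryid = raw$primaryid, outc_cod = toupper(raw$outc_cod))
  bad <- is.na(tbl$primaryid) | !tbl$outc_cod %in% outcome_codes
  list(tbl = tbl, bad = bad)
}

parse_ther <- function(raw) {
  tbl <- tibble(
    primaryid = raw$primaryid,
    dsg_drug_seq = suppressWarnings(as.integer(raw$dsg_drug_seq)),
    start_dt = parse_faers_date(raw$start_dt, partial = TRUE)
  )
  bad <- is.na(tbl$primaryid) | is.na(tbl$dsg_drug_seq)
  list(tbl = tbl, bad = bad)
}

#' Read deleted-case lists
#'
#' Each FAERS quarterly package ships a list of deleted case identifiers, one
#' per line. Reads one or more such files and returns the union of trimmed,
#' non-blank ids.
#'
#' @param paths Character vector of file paths.
#' @return Character vector of unique case ids (possibly empty).
#' @export
read_deleted_cases <- function(paths) {
  if (!length(paths)) return(character())
  ids <- purrr::map(paths, function(p) {
    if (!file.exists(p)) {
      abort(paste0("Deleted-case list not found: ", p), class = "faersignal_error_io")
    }
    readr::read_lines(p, progress = FALSE)
  })
  ids <- stringr::str_trim(unlist(ids))
  unique(ids[ids != ""])
}

# columns of the signal CSV, in contract order
signal_table_columns <- c(
  "level", "event", "soc_code", "a",
  "ror", "ror_low", "ror_high",
  "prr", "prr_low", "prr_high",
  "chi2", "ic_raw", "ic_expect", "ic025",
  "ebgm", "ebgm_low", "ebgm_high",
  "ror_signal", "prr_signal", "bcpnn_signal", "ebgm_signal", "all_four"
)

#' Write a disproportionality signal table to CSV
#'
#' Serializes the result of [analyze_all()] (or any tibble with the same
#' columns) with the fixed column order used by the pipeline outputs.
#' Statistics and confidence-interval bounds are rendered with two decimals,
#' matching the presentation of published signal tables.
#'
#' @param results Tibble of disproportionality results; may have zero rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(results, path) {
  num_cols <- c("ror", "ror_low", "ror_high", "prr", "prr_low", "prr_high",
                "chi2", "ic_raw", "ic_expect", "ic025",
                "ebgm", "ebgm_low", "ebgm_high")
  out <- as_tibble(results)
  for (col in setdiff(signal_table_columns, names(out))) out[[col]] <- NA
  out <- out[signal_table_columns]
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::all_of(num_cols),
                  ~ ifelse(is.finite(.x), formatC(round_half_up(.x, 2),
                                                  format = "f", digits = 2),
                           as.character(.x)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a descriptive summary to CSV
#'
#' @param summary A [summarize_reports()] result (tibble with columns
#'   `section`, `label`, `count`, `percent`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptives_table <- function(summary, path) {
  out <- as_tibble(summary)[c("section", "label", "count", "percent")]
  out$percent <- formatC(out$percent, format = "f", digits = 2)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
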