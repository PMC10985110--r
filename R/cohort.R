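# Target-drug cohort construction and MedDRA-style event aggregation.
# Events are analyzed at two levels: the preferred term (PT) itself, and the
# system organ class (SOC) each PT maps to under the primary-SOC convention.

#' Read a PT-to-SOC vocabulary mapping
#'
#' Loads a tab-separated file with columns `pt`, `soc_name`, `soc_code`
#' (a MedDRA-like mapping supplied by the user or emitted by the synthetic
#' generator; real MedDRA is licensed and never shipped). PT keys are
#' normalized with [normalize_term()]; each PT must map to exactly one SOC.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `pt`, `soc_name`, `soc_code` (integer),
#'   class `faers_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Vocabulary file not found: ", path), class = "faersignal_error_io")
  }
  v <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  names(v) <- tolower(names(v))
  need <- c("pt", "soc_name", "soc_code")
  if (!all(need %in% names(v))) {
    abort("Vocabulary file needs columns pt, soc_name, soc_code.",
          class = "faersignal_error_format")
  }
  vocabulary(v$pt, v$soc_name, v$soc_code)
}

#' Construct a PT-to-SOC vocabulary in memory
#'
#' @param pt Preferred-term text (normalized internally).
#' @param soc_name SOC display names.
#' @param soc_code Positive integer SOC codes.
#' @return A `faers_vocabulary` tibble.
#' @export
vocabulary <- function(pt, soc_name, soc_code) {
  v <- tibble(
    pt = normalize_term(pt),
    soc_name = stringr::str_squish(as.character(soc_name)),
    soc_code = as.integer(soc_code)
  ) %>% distinct(.data$pt, .keep_all = TRUE)
  if (any(is.na(v$soc_code)) || any(v$soc_code <= 0)) {
    abort("soc_code must be a positive integer for every PT.",
          class = "faersignal_error_format")
  }
  class(v) <- c("faers_vocabulary", class(v))
  v
}

#' Read a drug-synonym list
#'
#' One name per line (e.g. an active ingredient and its brand names); blank
#' lines ignored, names normalized.
#'
#' @param path Path to the synonym file.
#' @return Character vector of normalized drug names.
#' @export
read_drug_synonyms <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Synonym file not found: ", path), class = "faersignal_error_io")
  }
  x <- normalize_term(readr::read_lines(path, progress = FALSE))
  unique(x[x != ""])
}

#' Identify reports in which the target drug has a selected role
#'
#' A report belongs to the target cohort when any of its DRUG rows names the
#' target drug (matching either the verbatim `drugname` or the `prod_ai`
#' active-ingredient text, after normalization) in one of the selected role
#' codes — by default `PS`, the primary-suspect restriction. Reports that
#' carry the target drug only in a non-selected role (secondary suspect,
#' concomitant, interacting) are not selected and therefore count as
#' comparator reports downstream.
#'
#' @param drug Tibble of DRUG rows (`primaryid`, `drugname`, `prod_ai`,
#'   `role_cod`).
#' @param names Character vector of target drug names/synonyms (normalized
#'   internally); must be non-empty.
#' @param roles Role codes that qualify; default `"PS"`.
#' @return Character vector of target `primaryid`s.
#' @export
select_target_reports <- function(drug, names, roles = "PS") {
  names <- normalize_term(names)
  names <- names[names != ""]
  if (!length(names)) {
    abort("`names` must contain at least one drug name.",
          class = "faersignal_error_config")
  }
  drug <- as_tibble(drug)
  if (!nrow(drug)) return(character())
  hit <- (normalize_term(drug$drugname) %in% names |
            normalize_term(drug$prod_ai) %in% names) &
    drug$role_cod %in% roles
  unique(drug$primaryid[hit])
}

#' Count unique (report, event) pairs by target status
#'
#' The counting unit of the whole analysis is the unique (report, event)
#' pair: a report mentioning the same PT twice contributes once, and at SOC
#' level a report with several PTs inside one SOC contributes once to that
#' SOC. Reports are partitioned into target vs comparator by membership in
#' `target_ids`. PTs without a vocabulary entry at SOC level are pooled
#' under `"UNMAPPED"` (with a warning) rather than dropped, so the 2x2
#' margins are preserved.
#'
#' @param reac Tibble of REAC rows restricted to kept reports
#'   (`primaryid`, `pt`).
#' @param target_ids Character vector of target-report `primaryid`s.
#' @param vocab A `faers_vocabulary` (required for `level = "soc"`).
#' @param level `"pt"` or `"soc"`.
#' @return A `pair_counts` object: list with `level`, `target` and `other`
#'   count tibbles (`event`, `count`), `n_target_pairs`, `n_other_pairs`.
#' @export
build_pair_counts <- function(reac, target_ids, vocab = NULL,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  reac <- as_tibble(reac)
  ev <- tibble(primaryid = reac$primaryid, event = normalize_term(reac$pt))
  if (level == "soc") {
    if (is.null(vocab)) {
      abort("SOC-level counting requires a vocabulary.",
            class = "faersignal_error_config")
    }
    ev <- ev %>%
      left_join(as_tibble(vocab)[c("pt", "soc_name")],
                by = c(event = "pt")) %>%
      mutate(event = dplyr::coalesce(.data$soc_name, "UNMAPPED")) %>%
      select("primaryid", "event")
    n_unmapped <- sum(ev$event == "UNMAPPED")
    if (n_unmapped > 0) {
      issue_warning(
        paste0(n_unmapped, " reaction row(s) had PTs absent from the ",
               "vocabulary; pooled under 'UNMAPPED'."),
        "faersignal_warning_unmapped_pt"
      )
    }
  }
  ev <- distinct(ev)   # one contribution per (report, event)
  ev$is_target <- ev$primaryid %in% target_ids
  tab <- function(x) {
    if (!nrow(x)) return(tibble(event = character(), count = integer()))
    count(x, .data$event, name = "count") %>% arrange(.data$event)
  }
  target <- tab(ev[ev$is_target, ])
  other <- tab(ev[!ev$is_target, ])
  structure(
    list(
      level = level,
      target = target,
      other = other,
      n_target_pairs = sum(target$count),
      n_other_pairs = sum(other$count)
    ),
    class = "pair_counts"
  )
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> level:", x$level,
      "| target events:", nrow(x$target), "(", x$n_target_pairs, "pairs )",
      "| comparator events:", nrow(x$other), "(", x$n_other_pairs, "pairs )\n")
  invisible(x)
}
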