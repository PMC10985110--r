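# Synthetic FAERS-like data with known ground truth. The generator emulates
# the structural features of real quarterly extracts that the pipeline has to
# survive: duplicate case versions across quarters, a deleted-case list,
# primary-suspect vs concomitant roles, heavy demographic missingness, and
# multi-PT reports — plus configurable per-(drug, PT) reporting-rate
# multipliers so that signal-recovery can be checked against a closed form.

default_drug_vocab <- function() {
  tibble(
    drug = c("LEVODOPA", "CARBIDOPA", "PRAMIPEXOLE", "ROPINIROLE",
             "AMANTADINE", "RASAGILINE", "METFORMIN", "ATORVASTATIN",
             "LISINOPRIL", "OMEPRAZOLE", "SERTRALINE", "GABAPENTIN",
             "IBUPROFEN", "ASPIRIN", "WARFARIN", "INSULIN GLARGINE",
             "AMLODIPINE", "LEVOTHYROXINE", "PREDNISONE"),
    prob = c(0.10, 0.08, 0.05, 0.05, 0.04, 0.03, 0.08, 0.08,
             0.07, 0.07, 0.06, 0.05, 0.05, 0.05, 0.04, 0.04,
             0.04, 0.04, 0.03)
  )
}

default_event_vocab <- function() {
  nervous <- c("DIZZINESS", "HEADACHE", "SOMNOLENCE", "TREMOR", "DYSKINESIA",
               "FREEZING PHENOMENON", "PARKINSONISM HYPERPYREXIA SYNDROME")
  psych <- c("INSOMNIA", "HALLUCINATION", "ANXIETY", "CONFUSIONAL STATE",
             "COMPULSIONS", "SLEEP TALKING")
  gastro <- c("NAUSEA", "VOMITING", "DIARRHOEA", "CONSTIPATION")
  general <- c("FATIGUE", "ASTHENIA", "GAIT DISTURBANCE", "FALL",
               "DRUG INEFFECTIVE")
  cardiac <- c("PALPITATIONS", "ATRIAL FIBRILLATION")
  skin <- c("RASH", "PRURITUS")
  invest <- c("WEIGHT DECREASED", "BLOOD PRESSURE INCREASED")
  surg <- c("DEEP BRAIN STIMULATION", "EMERGENCY CARE")
  v <- dplyr::bind_rows(
    tibble(pt = nervous, soc_name = "Nervous system disorders", soc_code = 10029205L),
    tibble(pt = psych, soc_name = "Psychiatric disorders", soc_code = 10037175L),
    tibble(pt = gastro, soc_name = "Gastrointestinal disorders", soc_code = 10017947L),
    tibble(pt = general, soc_name = "General disorders and administration site conditions",
           soc_code = 10018065L),
    tibble(pt = cardiac, soc_name = "Cardiac disorders", soc_code = 10007541L),
    tibble(pt = skin, soc_name = "Skin and subcutaneous tissue disorders",
           soc_code = 10040785L),
    tibble(pt = invest, soc_name = "Investigations", soc_code = 10022891L),
    tibble(pt = surg, soc_name = "Surgical and medical procedures",
           soc_code = 10042613L)
  )
  base <- c(0.06, 0.05, 0.03, 0.03, 0.02, 0.0008, 0.0004,
            0.04, 0.03, 0.03, 0.02, 0.0015, 0.004,
            0.07, 0.04, 0.03, 0.02,
            0.08, 0.04, 0.03, 0.05, 0.06,
            0.02, 0.01,
            0.03, 0.02,
            0.02, 0.02,
            0.0007, 0.001)
  v$prob <- base / sum(base)
  v
}

#' Configuration for the synthetic FAERS-like generator
#'
#' Defaults emulate the shape of a recent-drug pharmacovigilance cohort:
#' 50,000 reports over 15 quarters; a target drug present (as primary
#' suspect) in 2% of reports; ~2 preferred terms per report; demographic
#' missingness at spontaneous-reporting levels (98.5% unknown sex and age,
#' pharmacists dominating the reporter mix); a 5% duplicate-version rate and
#' 1% deleted-case rate; and three injected reporting-rate multipliers
#' (rho = 10, 5, 2) on rare PTs of the target drug.
#'
#' @param n_reports Number of distinct cases.
#' @param n_quarters Number of calendar quarters spanned (from 2019 Q3).
#' @param duplicate_rate Probability a case receives a second version.
#' @param duplicate_tie_rate Fraction of duplicate versions sharing the
#'   original FDA receipt date (exercises the PRIMARYID tie-break);
#'   otherwise the second version's date is strictly later.
#' @param deleted_rate Probability a case appears on the deleted list.
#' @param drug_vocab Tibble `drug`, `prob` of comparator primary-suspect
#'   drugs.
#' @param target_drug Normalized target drug (active ingredient) name.
#' @param target_synonyms Names under which the target appears in
#'   `drugname` (brand and generic).
#' @param target_prevalence Probability a report's primary suspect is the
#'   target drug.
#' @param event_vocab Tibble `pt`, `soc_name`, `soc_code`, `prob` of
#'   baseline PT reporting probabilities.
#' @param signal_effects Tibble `drug`, `pt`, `rho` of relative
#'   reporting-rate multipliers (rho > 0), or `NULL` for the null model.
#' @param pts_per_report List `mean`, `max` for the per-report PT count
#'   (1 + Poisson(mean - 1), capped).
#' @param missingness Per-field missingness probabilities: `sex`, `age`,
#'   `occp`, `country`, `event_dt`, `start_dt`.
#' @param occp_probs Reporter-occupation mix (`MD`, `PH`, `CN`, `HP`, `OT`).
#' @param country_probs Occurrence-country mix.
#' @param outcome_rates Per-report probabilities of each serious-outcome
#'   code.
#' @param concomitant_rate Probability a report carries one extra
#'   concomitant (role `C`) drug row.
#' @param seed RNG seed; identical seed gives byte-identical output.
#' @return Validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_reports = 50000,
    n_quarters = 15,
    duplicate_rate = 0.05,
    duplicate_tie_rate = 0,
    deleted_rate = 0.01,
    drug_vocab = default_drug_vocab(),
    target_drug = "ISTRADEFYLLINE",
    target_synonyms = c("ISTRADEFYLLINE", "NOURIANZ"),
    target_prevalence = 0.02,
    event_vocab = default_event_vocab(),
    signal_effects = tibble(
      drug = "ISTRADEFYLLINE",
      pt = c("FREEZING PHENOMENON", "COMPULSIONS", "SLEEP TALKING"),
      rho = c(10, 5, 2)
    ),
    pts_per_report = list(mean = 2, max = 6),
    missingness = list(sex = 0.985, age = 0.985, occp = 0.003,
                       country = 0.003, event_dt = 0.5, start_dt = 0.55),
    occp_probs = c(MD = 0.0165, PH = 0.8775, CN = 0.084, HP = 0.0145,
                   OT = 0.0075),
    country_probs = c(US = 0.9876, JP = 0.0088, DE = 0.0036),
    outcome_rates = c(DE = 0.1068, HO = 0.0823, DS = 0.003, LT = 0.0022,
                      OT = 0.03),
    concomitant_rate = 0.3,
    seed = 1L) {
  cfg <- list(
    n_reports = n_reports, n_quarters = n_quarters,
    duplicate_rate = duplicate_rate, duplicate_tie_rate = duplicate_tie_rate,
    deleted_rate = deleted_rate, drug_vocab = as_tibble(drug_vocab),
    target_drug = normalize_term(target_drug),
    target_synonyms = normalize_term(target_synonyms),
    target_prevalence = target_prevalence,
    event_vocab = dplyr::mutate(as_tibble(event_vocab),
                                pt = normalize_term(.data$pt)),
    signal_effects = if (is.null(signal_effects)) {
      tibble(drug = character(), pt = character(), rho = numeric())
    } else {
      dplyr::mutate(as_tibble(signal_effects),
                    drug = normalize_term(.data$drug),
                    pt = normalize_term(.data$pt))
    },
    pts_per_report = pts_per_report, missingness = missingness,
    occp_probs = occp_probs, country_probs = country_probs,
    outcome_rates = outcome_rates, concomitant_rate = concomitant_rate,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(paste0("Invalid synthetic config field `", field, "`: ", msg),
          class = "faersignal_error_config")
  }
  if (!is.numeric(cfg$n_reports) || cfg$n_reports < 1) {
    bad("n_reports", "must be a positive count")
  }
  probs <- c(duplicate_rate = cfg$duplicate_rate,
             duplicate_tie_rate = cfg$duplicate_tie_rate,
             deleted_rate = cfg$deleted_rate,
             target_prevalence = cfg$target_prevalence,
             concomitant_rate = cfg$concomitant_rate,
             unlist(cfg$missingness))
  for (nm in names(probs)) {
    if (is.na(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1) {
      bad(nm, "must be a probability in [0, 1]")
    }
  }
  if (nrow(cfg$signal_effects) && any(cfg$signal_effects$rho <= 0)) {
    bad("signal_effects", "rho must be > 0")
  }
  if (any(cfg$event_vocab$prob < 0) || sum(cfg$event_vocab$prob) <= 0) {
    bad("event_vocab", "probabilities must be non-negative and normalizable")
  }
  if (any(duplicated(cfg$event_vocab$pt))) {
    bad("event_vocab", "duplicate PT entries")
  }
  if (cfg$pts_per_report$mean < 1 || cfg$pts_per_report$max < 1) {
    bad("pts_per_report", "mean and max must be >= 1")
  }
  invisible(cfg)
}

#' Closed-form expected relative reporting rates
#'
#' For each PT, the expected ratio between the PT's share of target-report
#' (report, event) pairs and its share of comparator pairs, under the
#' generator's model. Target reports draw PTs with probabilities
#' `b_i * rho_i` renormalized, so the relative rate for PT `i` is
#' `rho_i / Z` with `Z = sum_j p_j rho_j` (baseline probabilities `p`
#' normalized). For rare PTs with an injected effect this is within a
#' renormalization correction of `rho_i` itself. ROR and PRR estimate this
#' target-vs-comparator rate directly (for rare PTs); the
#' observed-to-expected ratio EBGM instead compares the target rate against
#' the whole database including the target's own reports, so its estimand is
#' the attenuated `expected_ebgm = r / (1 - f + f * r)` where `r` is
#' `expected_rate` and `f` the target share of reports — returned alongside
#' so each estimator is checked against the quantity it estimates.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble `pt`, `rho`, `expected_rate`, `expected_ebgm`.
#' @export
expected_pair_rates <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ev <- cfg$event_vocab
  p <- ev$prob / sum(ev$prob)
  eff <- dplyr::filter(cfg$signal_effects, .data$drug == cfg$target_drug)
  rho <- ifelse(ev$pt %in% eff$pt, eff$rho[match(ev$pt, eff$pt)], 1)
  z <- sum(p * rho)
  f <- cfg$target_prevalence
  r <- rho / z
  tibble(pt = ev$pt, rho = rho, expected_rate = r,
         expected_ebgm = r / (1 - f + f * r))
}

#' Generate a synthetic FAERS-like dataset
#'
#' Draws `n_reports` cases under the model described in
#' [synthetic_config()] and returns in-memory tables in the exact shape
#' produced by [read_faers_table()]; with `dir` set, also writes the five
#' "$"-delimited tables plus the deleted-case list, the PT-to-SOC vocabulary
#' (TSV) and the drug-synonym list. Output is a deterministic function of
#' the config (including its seed).
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A `faers_synthetic` list: `tables` (demo/drug/reac/outc/ther
#'   tibbles), `deleted` (case ids), `vocabulary`, `synonyms`, `truth`
#'   (expected rates, duplicate/deleted ledgers, per-case assignments), and
#'   `paths` when written.
#' @export
generate_faers_dataset <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_impl(cfg, dir))
}

generate_impl <- function(cfg, dir) {
  n <- as.integer(cfg$n_reports)
  caseid <- as.character(1000000L + seq_len(n))

  first_day <- as.Date("2019-07-01")
  last_day <- seq(first_day, by = "quarter", length.out = cfg$n_quarters + 1)[cfg$n_quarters + 1] - 1
  fda_dt <- sample(seq(first_day, last_day, by = "day"), n, replace = TRUE)

  is_target <- runif(n) < cfg$target_prevalence
  drugname <- character(n)
  n_t <- sum(is_target)
  drugname[is_target] <- sample(cfg$target_synonyms, n_t, replace = TRUE)
  drugname[!is_target] <- sample(cfg$drug_vocab$drug, n - n_t, replace = TRUE,
                                 prob = cfg$drug_vocab$prob)
  prod_ai <- ifelse(is_target, cfg$target_drug, drugname)

  # per-report PT draws: baseline probabilities, multiplied by rho and
  # renormalized for target reports; draws with replacement, deduplicated
  # within report
  ev <- cfg$event_vocab
  p_other <- ev$prob / sum(ev$prob)
  rates <- expected_pair_rates(cfg)
  p_target <- p_other * rates$rho
  p_target <- p_target / sum(p_target)
  k <- pmin(1L + rpois(n, cfg$pts_per_report$mean - 1), cfg$pts_per_report$max)
  rep_idx <- rep.int(seq_len(n), k)
  tgt_draw <- is_target[rep_idx]
  pt_idx <- integer(length(rep_idx))
  pt_idx[tgt_draw] <- sample.int(nrow(ev), sum(tgt_draw), replace = TRUE,
                                 prob = p_target)
  pt_idx[!tgt_draw] <- sample.int(nrow(ev), sum(!tgt_draw), replace = TRUE,
                                  prob = p_other)
  reac_case <- distinct(tibble(case_i = rep_idx, pt = ev$pt[pt_idx]))

  # demographics with heavy missingness
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55))
  sex[runif(n) < cfg$missingness$sex] <- NA_character_
  age_years <- pmax(pmin(round(rnorm(n, 71, 10)), 100), 18)
  age_unit <- sample(c("YR", "MON", "DEC"), n, replace = TRUE,
                     prob = c(0.95, 0.03, 0.02))
  age <- dplyr::case_when(
    age_unit == "YR" ~ as.numeric(age_years),
    age_unit == "MON" ~ as.numeric(age_years * 12),
    age_unit == "DEC" ~ age_years / 10
  )
  drop_age <- runif(n) < cfg$missingness$age
  age[drop_age] <- NA_real_
  age_unit[drop_age] <- NA_character_
  occp <- sample(names(cfg$occp_probs), n, replace = TRUE,
                 prob = cfg$occp_probs)
  occp[runif(n) < cfg$missingness$occp] <- NA_character_
  country <- sample(names(cfg$country_probs), n, replace = TRUE,
                    prob = cfg$country_probs)
  country[runif(n) < cfg$missingness$country] <- NA_character_

  # therapy and onset dates (event after start; onset mass concentrated
  # in the first weeks, long tail)
  start_dt <- fda_dt - sample(30:400, n, replace = TRUE)
  gap_bin <- sample.int(4L, n, replace = TRUE, prob = c(0.35, 0.15, 0.12, 0.38))
  gap <- c(0L, 7L, 28L, 60L)[gap_bin] +
    floor(runif(n) * c(7, 21, 32, 300)[gap_bin])
  event_dt <- start_dt + gap
  event_dt[runif(n) < cfg$missingness$event_dt] <- as.Date(NA)
  start_missing <- runif(n) < cfg$missingness$start_dt

  # duplicate versions and deleted cases
  dup <- runif(n) < cfg$duplicate_rate
  tie <- dup & runif(n) < cfg$duplicate_tie_rate
  deleted <- runif(n) < cfg$deleted_rate
  pid1 <- paste0(caseid, "1")
  pid2 <- paste0(caseid, "2")
  fda2 <- fda_dt + ifelse(tie, 0L, sample(1:90, n, replace = TRUE))
  kept_pid <- ifelse(dup, pid2, pid1)
  kept_fda <- as.Date(ifelse(dup, fda2, fda_dt), origin = "1970-01-01")

  demo_of <- function(pids, fdas, idx) {
    tibble(
      primaryid = pids, caseid = caseid[idx], fda_dt = fdas,
      event_dt = event_dt[idx], age = age[idx], age_unit = age_unit[idx],
      sex = sex[idx], occp_cod = occp[idx], occr_country = country[idx],
      report_year = as.integer(format(fdas, "%Y"))
    )
  }
  demo <- bind_rows(
    demo_of(pid1, fda_dt, seq_len(n)),
    demo_of(pid2[dup], fda2[dup], which(dup))
  ) %>% arrange(.data$caseid, .data$primaryid)

  per_version <- tibble(
    case_i = c(seq_len(n), which(dup)),
    primaryid = c(pid1, pid2[dup])
  )

  drug_one <- tibble(
    case_i = seq_len(n), drug_seq = 1L, drugname = drugname,
    prod_ai = prod_ai, role_cod = "PS"
  )
  con <- which(runif(n) < cfg$concomitant_rate)
  drug_con <- tibble(
    case_i = con, drug_seq = 2L,
    drugname = sample(cfg$drug_vocab$drug, length(con), replace = TRUE,
                      prob = cfg$drug_vocab$prob),
    prod_ai = NA_character_, role_cod = "C"
  )
  drug_case <- bind_rows(drug_one, drug_con)
  drug <- dplyr::inner_join(per_version, drug_case, by = "case_i",
                            relationship = "many-to-many") %>%
    select("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod") %>%
    arrange(.data$primaryid, .data$drug_seq)

  reac <- dplyr::inner_join(per_version, reac_case, by = "case_i",
                            relationship = "many-to-many") %>%
    select("primaryid", "pt") %>%
    arrange(.data$primaryid, .data$pt)

  outc_case <- purrr::imap(cfg$outcome_rates, function(rate, code) {
    tibble(case_i = which(runif(n) < rate), outc_cod = code)
  }) %>% bind_rows()
  outc <- dplyr::inner_join(per_version, outc_case, by = "case_i",
                            relationship = "many-to-many") %>%
    select("primaryid", "outc_cod") %>%
    arrange(.data$primaryid, .data$outc_cod)

  ther_case <- tibble(case_i = which(!start_missing), dsg_drug_seq = 1L,
                      start_dt = start_dt[!start_missing])
  ther <- dplyr::inner_join(per_version, ther_case, by = "case_i",
                            relationship = "many-to-many") %>%
    select("primaryid", "dsg_drug_seq", "start_dt") %>%
    arrange(.data$primaryid)

  truth <- list(
    expected_rates = rates,
    duplicate_cases = caseid[dup],
    deleted_cases = caseid[deleted],
    assignments = tibble(caseid = caseid, primaryid_kept = kept_pid,
                         fda_dt_kept = kept_fda, is_target = is_target)
  )

  out <- structure(
    list(
      tables = list(demo = demo, drug = drug, reac = reac, outc = outc,
                    ther = ther),
      deleted = caseid[deleted],
      vocabulary = vocabulary(ev$pt, ev$soc_name, ev$soc_code),
      synonyms = cfg$target_synonyms,
      truth = truth,
      config = cfg,
      paths = NULL
    ),
    class = "faers_synthetic"
  )
  if (!is.null(dir)) out$paths <- write_synthetic(out, dir)
  out
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))
fmt_chr <- function(x) ifelse(is.na(x), "", as.character(x))

write_dollar <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), fmt_chr))
  lines <- c(paste(names(df), collapse = "$"),
             do.call(paste, c(unname(as.list(df)), sep = "$")))
  readr::write_lines(lines, path)
  path
}

write_synthetic <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- x$tables
  paths <- list(
    demo = file.path(dir, "demo.txt"),
    drug = file.path(dir, "drug.txt"),
    reac = file.path(dir, "reac.txt"),
    outc = file.path(dir, "outc.txt"),
    ther = file.path(dir, "ther.txt"),
    deleted = file.path(dir, "deleted_cases.txt"),
    vocabulary = file.path(dir, "vocabulary.tsv"),
    synonyms = file.path(dir, "synonyms.txt")
  )
  write_dollar(dplyr::mutate(t$demo,
                             fda_dt = fmt_date(.data$fda_dt),
                             event_dt = fmt_date(.data$event_dt)) %>%
                 select(-"report_year") %>%
                 rename(age_cod = "age_unit"),
               paths$demo)
  write_dollar(t$drug, paths$drug)
  write_dollar(t$reac, paths$reac)
  write_dollar(t$outc, paths$outc)
  write_dollar(dplyr::mutate(t$ther, start_dt = fmt_date(.data$start_dt)),
               paths$ther)
  readr::write_lines(x$deleted, paths$deleted)
  readr::write_tsv(as_tibble(x$vocabulary), paths$vocabulary, progress = FALSE)
  readr::write_lines(x$synonyms, paths$synonyms)
  paths
}

#' @export
print.faers_synthetic <- function(x, ...) {
  cat("<faers_synthetic>", nrow(x$truth$assignments), "cases;",
      nrow(x$tables$demo), "DEMO rows;",
      length(x$truth$duplicate_cases), "duplicated;",
      length(x$truth$deleted_cases), "deleted;",
      sum(x$truth$assignments$is_target), "target reports\n")
  invisible(x)
}
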