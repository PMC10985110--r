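# End-to-end orchestration: raw tables -> deduplicated cohort -> descriptive
# summary + PT/SOC signal tables, with a stage-count ledger.

load_table <- function(x, kind) {
  if (is.character(x) && length(x) == 1) read_faers_table(x, kind)
  else as_tibble(x)
}

stage_log <- function(quiet, name, n_in, n_out) {
  if (!quiet) message(sprintf("stage=%s in=%d out=%d", name, n_in, n_out))
}

#' Run the full disproportionality analysis
#'
#' Executes the complete pipeline: read the five FAERS-style tables,
#' deduplicate case versions (latest FDA receipt date, then largest report
#' id), remove deleted cases, restrict child tables to kept report versions,
#' select target-drug reports by primary-suspect (or configured) role, build
#' unique (report, event) pair counts at PT and/or SOC level, summarize the
#' cohort's descriptive characteristics, and compute all four
#' disproportionality statistics with signal flags for every event in the
#' target margin.
#'
#' @param demo,drug,reac,outc,ther Each either a file path (read with
#'   [read_faers_table()]) or an already-typed tibble. `outc` and `ther`
#'   are optional (`NULL` skips outcomes / onset sections gracefully).
#' @param deleted Character vector: paths to deleted-case list files (when
#'   the files exist) or literal case ids.
#' @param vocab A `faers_vocabulary`, or a path to a vocabulary TSV, or
#'   `NULL` (PT level only).
#' @param drug_names Target drug names/synonyms, or a path to a synonym
#'   file.
#' @param roles Qualifying drug role codes (default `"PS"`).
#' @param level `"pt"`, `"soc"`, or `"both"`.
#' @param criteria,hp,yates Passed to [analyze_all()].
#' @param out_dir If non-`NULL`, writes `descriptives.csv`,
#'   `signals_pt.csv`, `signals_soc.csv` and `run_log.txt` there.
#' @param quiet Suppress `stage=<name> in=<n> out=<m>` progress messages.
#' @return A `faers_analysis` object: list with `descriptives`,
#'   `signals_pt`, `signals_soc` (either may be `NULL` depending on
#'   `level`), and `counts` (named stage ledger satisfying
#'   `reports_read = kept + duplicates_removed + deleted_removed`).
#' @export
run_faers_analysis <- function(demo, drug, reac, outc = NULL, ther = NULL,
                               deleted = character(), vocab = NULL,
                               drug_names, roles = "PS",
                               level = c("both", "pt", "soc"),
                               criteria = signal_criteria(),
                               hp = bcpnn_priors(), yates = FALSE,
                               out_dir = NULL, quiet = FALSE) {
  level <- match.arg(level)
  demo <- load_table(demo, "demo")
  drug <- load_table(drug, "drug")
  reac <- load_table(reac, "reac")
  if (!is.null(outc)) outc <- load_table(outc, "outc")
  if (!is.null(ther)) ther <- load_table(ther, "ther")
  if (length(deleted) && all(file.exists(deleted))) {
    deleted <- read_deleted_cases(deleted)
  }
  if (is.character(vocab) && length(vocab) == 1) {
    vocab <- read_vocabulary(vocab)
  }
  if (is.character(drug_names) && length(drug_names) == 1 &&
      file.exists(drug_names)) {
    drug_names <- read_drug_synonyms(drug_names)
  }
  drug_names <- normalize_term(drug_names)

  n_read <- nrow(demo)
  kept <- deduplicate_reports(demo)
  n_dup <- attr(kept, "removed_as_duplicate")
  stage_log(quiet, "deduplicate", n_read, nrow(kept))
  kept <- drop_deleted(kept, deleted)
  n_del <- attr(kept, "removed_as_deleted")
  stage_log(quiet, "drop_deleted", n_read - n_dup, nrow(kept))

  drug_k <- filter_to_kept(drug, kept)
  reac_k <- filter_to_kept(reac, kept)
  outc_k <- if (!is.null(outc)) filter_to_kept(outc, kept)
  ther_k <- if (!is.null(ther)) filter_to_kept(ther, kept)

  target_ids <- select_target_reports(drug_k, drug_names, roles)
  stage_log(quiet, "select_target", nrow(kept), length(target_ids))

  cohort <- assemble_cohort(kept[kept$primaryid %in% target_ids, ],
                            outc_k, ther_k, drug_k, drug_names)
  descriptives <- if (nrow(cohort)) summarize_reports(cohort)

  analyze_level <- function(lv) {
    pc <- build_pair_counts(reac_k, target_ids, vocab = vocab, level = lv)
    stage_log(quiet, paste0("pairs_", lv),
              pc$n_target_pairs + pc$n_other_pairs, nrow(pc$target))
    analyze_all(pc, vocab = vocab, hp = hp, criteria = criteria,
                yates = yates)
  }
  signals_pt <- if (level %in% c("pt", "both")) analyze_level("pt")
  signals_soc <- if (level %in% c("soc", "both") && !is.null(vocab)) {
    analyze_level("soc")
  }

  counts <- c(
    reports_read = n_read,
    duplicates_removed = n_dup,
    deleted_removed = n_del,
    kept = nrow(kept),
    target_reports = length(target_ids),
    n_target_pairs_pt = if (!is.null(signals_pt)) sum(signals_pt$a) else NA,
    n_target_pairs_soc = if (!is.null(signals_soc)) sum(signals_soc$a) else NA
  )

  res <- structure(
    list(descriptives = descriptives, signals_pt = signals_pt,
         signals_soc = signals_soc, counts = counts, cohort = cohort),
    class = "faers_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(descriptives)) {
      write_descriptives_table(descriptives,
                               file.path(out_dir, "descriptives.csv"))
    }
    if (!is.null(signals_pt)) {
      write_signal_table(signals_pt, file.path(out_dir, "signals_pt.csv"))
    }
    if (!is.null(signals_soc)) {
      write_signal_table(signals_soc, file.path(out_dir, "signals_soc.csv"))
    }
    readr::write_lines(
      paste0(names(counts), "=", unname(counts)),
      file.path(out_dir, "run_log.txt")
    )
  }
  res
}

#' @export
print.faers_analysis <- function(x, ...) {
  cat("FAERS-style disproportionality analysis\n")
  cat("  reports read:", x$counts[["reports_read"]],
      "| kept:", x$counts[["kept"]],
      "| target:", x$counts[["target_reports"]], "\n")
  if (!is.null(x$signals_pt)) {
    cat("  PT-level events analyzed:", nrow(x$signals_pt),
        "| all-four signals:", sum(x$signals_pt$all_four), "\n")
  }
  if (!is.null(x$signals_soc)) {
    cat("  SOC-level events analyzed:", nrow(x$signals_soc),
        "| all-four signals:", sum(x$signals_soc$all_four), "\n")
  }
  invisible(x)
}

#' Tidy a pipeline result into one signal tibble
#'
#' @param x A `faers_analysis` object.
#' @param ... Unused.
#' @return The PT- and SOC-level signal rows stacked into one tibble.
#' @exportS3Method generics::tidy
tidy.faers_analysis <- function(x, ...) {
  bind_rows(x$signals_pt, x$signals_soc)
}

#' One-row pipeline overview
#'
#' @param x A `faers_analysis` object.
#' @param ... Unused.
#' @return One-row tibble: stage ledger counts plus the number of events
#'   flagged by all four methods at each level.
#' @exportS3Method generics::glance
glance.faers_analysis <- function(x, ...) {
  tibble(
    reports_read = x$counts[["reports_read"]],
    duplicates_removed = x$counts[["duplicates_removed"]],
    deleted_removed = x$counts[["deleted_removed"]],
    kept = x$counts[["kept"]],
    target_reports = x$counts[["target_reports"]],
    events_pt = if (!is.null(x$signals_pt)) nrow(x$signals_pt) else NA_integer_,
    events_soc = if (!is.null(x$signals_soc)) nrow(x$signals_soc) else NA_integer_,
    signals_pt = if (!is.null(x$signals_pt)) sum(x$signals_pt$all_four) else NA_integer_,
    signals_soc = if (!is.null(x$signals_soc)) sum(x$signals_soc$all_four) else NA_integer_
  )
}

#' Forest plot of disproportionality signals
#'
#' Reporting odds ratios with 95% confidence intervals on a log scale, one
#' row per event (top `max_events` by EBGM), colored by whether all four
#' methods flag the event.
#'
#' @param object A `faers_signals` tibble from [analyze_all()].
#' @param max_events Number of top events to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.faers_signals <- function(object, max_events = 30, ...) {
  df <- head(dplyr::arrange(object, desc(.data$ebgm)), max_events)
  df$event <- factor(df$event, levels = rev(df$event))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event,
                                   color = .data$all_four)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ror_low,
                                          xmax = .data$ror_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  color = "All four\nmethods") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.faers_signals
#' @exportS3Method ggplot2::autoplot
autoplot.faers_analysis <- function(object, max_events = 30, ...) {
  sig <- object$signals_pt %||% object$signals_soc
  autoplot(sig, max_events = max_events, ...)
}

#' Bar charts of cohort descriptive sections
#'
#' @param object A `descriptive_summary` from [summarize_reports()].
#' @param ... Unused.
#' @return A ggplot object faceted by section.
#' @exportS3Method ggplot2::autoplot
autoplot.descriptive_summary <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~section, scales = "free_y") +
    ggplot2::labs(x = "% of reports", y = NULL) +
    ggplot2::theme_minimal()
}
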