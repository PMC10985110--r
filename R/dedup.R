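# Case-level deduplication. FAERS reports arrive in versions: the same CASEID
# can appear in several quarters under different PRIMARYIDs. Following the
# FDA-recommended rule, one row is kept per case: the version with the latest
# FDA receipt date, ties broken by the largest PRIMARYID.

#' Deduplicate DEMO report versions to one row per case
#'
#' For each `caseid`, keeps the row with the maximum `fda_dt`; among ties on
#' `fda_dt`, the row with the largest `primaryid` (numeric order when all ids
#' are digit strings, lexicographic otherwise). Output is sorted by `caseid`,
#' so the result is independent of input row order, and the operation is
#' idempotent.
#'
#' @param demo Tibble of DEMO rows as returned by
#'   [read_faers_table()] (needs `primaryid`, `caseid`, `fda_dt`).
#' @return The kept rows, one per case, with attribute
#'   `removed_as_duplicate` giving the number of discarded versions.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("1", "2"), caseid = c("55", "55"),
#'   fda_dt = as.Date(c("2020-01-01", "2020-03-01"))
#' )
#' deduplicate_reports(demo)
#' @export
deduplicate_reports <- function(demo) {
  demo <- as_tibble(demo)
  if (!nrow(demo)) {
    res <- demo
    attr(res, "removed_as_duplicate") <- 0L
    return(res)
  }
  kept <- demo %>%
    mutate(.idkey = id_order_key(.data$primaryid),
           .casekey = id_order_key(.data$caseid)) %>%
    arrange(.data$.casekey, desc(.data$fda_dt), desc(.data$.idkey)) %>%
    group_by(.data$caseid) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    arrange(.data$.casekey) %>%
    select(-".idkey", -".casekey")
  attr(kept, "removed_as_duplicate") <- nrow(demo) - nrow(kept)
  kept
}

#' Remove deleted cases from a deduplicated cohort
#'
#' FAERS quarterly packages include lists of case ids whose reports were
#' deleted; those cases are removed entirely (deletion is case-level).
#' Applied after [deduplicate_reports()], matching the pipeline's
#' dedup-then-delete order.
#'
#' @param demo Tibble of deduplicated DEMO rows.
#' @param deleted Character vector of deleted case ids (see
#'   [read_deleted_cases()]); unknown ids have no effect.
#' @return `demo` without the deleted cases, with attribute
#'   `removed_as_deleted` giving the number of rows removed.
#' @export
drop_deleted <- function(demo, deleted) {
  demo <- as_tibble(demo)
  keep <- !demo$caseid %in% deleted
  res <- demo[keep, , drop = FALSE]
  attr(res, "removed_as_deleted") <- sum(!keep)
  attr(res, "removed_as_duplicate") <- attr(demo, "removed_as_duplicate")
  res
}

#' Restrict child tables to kept report versions
#'
#' After deduplication and deleted-case removal, drops DRUG/REAC/OUTC/THER
#' rows whose `primaryid` no longer corresponds to a kept DEMO row.
#'
#' @param tbl A child table with a `primaryid` column.
#' @param demo The kept DEMO rows.
#' @return Filtered `tbl`.
#' @export
filter_to_kept <- function(tbl, demo) {
  dplyr::filter(as_tibble(tbl), .data$primaryid %in% demo$primaryid)
}
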