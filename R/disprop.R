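# Disproportionality statistics for 2x2 drug-event reporting tables.
#
# The table for one (drug, event) pair:
#                     target event   other events
#   target drug            a              b
#   other drugs            c              d
#
# a = reports with both the target drug and the event; margins a+b (all
# target-drug pairs) and a+c (all pairs with the event); N = a+b+c+d.
#
# Four statistics are computed per pair, each with its conventional
# screening threshold:
#   ROR  = ad/bc,              signal when a >= 3 and 95% CI lower bound > 1
#   PRR  = (a/(a+b))/(c/(c+d)), signal when a >= 3 and 95% CI lower bound > 1
#   BCPNN information component: E(IC), V(IC), IC025 = E(IC) - 2*sqrt(V(IC)),
#        signal when IC025 > 0
#   EBGM = aN/((a+b)(a+c)) (observed/expected relative reporting ratio),
#        signal when EBGM05 (95% CI lower bound) > 2
#
# Zero-cell policy: a statistic whose point estimate or CI divides by a zero
# cell is recomputed on the Haldane-Anscombe corrected table (all four cells
# + 0.5) for that statistic only, and the row is flagged `corrected`.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative cell counts (see the table layout in
#'   the package overview: `a` target drug & target event, `b` target drug &
#'   other events, `c` other drugs & target event, `d` other drugs & other
#'   events).
#' @return A `contingency_table` list with fields `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d))   # doubles: cell products overflow integers
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("All cells must be non-negative counts.",
          class = "faersignal_error_config")
  }
  structure(c(as.list(cells), list(n = sum(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 reporting table: a =", x$a, " b =", x$b, " c =", x$c,
      " d =", x$d, " N =", x$n, "\n")
  invisible(x)
}

#' Build the 2x2 table for one event from pair counts
#'
#' `a` is the target-report count for the event, `b = n_target_pairs - a`,
#' `c` the comparator count, `d = n_other_pairs - c`.
#'
#' @param pc A [build_pair_counts()] result.
#' @param event Event label (PT or SOC name, normalized form).
#' @return A `contingency_table`.
#' @export
build_contingency <- function(pc, event) {
  stopifnot(inherits(pc, "pair_counts"))
  a <- pc$target$count[match(event, pc$target$event)]
  c_ <- pc$other$count[match(event, pc$other$event)]
  a <- if (is.na(a)) 0L else a
  c_ <- if (is.na(c_)) 0L else c_
  contingency_table(a, pc$n_target_pairs - a, c_, pc$n_other_pairs - c_)
}

#' BCPNN prior hyperparameters
#'
#' Defaults are the classical BCPNN priors: joint prior count
#' `gamma11 = 1` with marginal priors `alpha = beta = 2`,
#' `alpha1 = beta1 = 1`, which make the prior information component centre
#' on 0 (independence). At database scale the marginal priors are numerically
#' irrelevant; `gamma11` sets the shrinkage of small counts.
#'
#' @param gamma11,alpha,alpha1,beta,beta1 Positive prior constants.
#' @return Named list of hyperparameters.
#' @export
bcpnn_priors <- function(gamma11 = 1, alpha = 2, alpha1 = 1,
                         beta = 2, beta1 = 1) {
  hp <- list(gamma11 = gamma11, alpha = alpha, alpha1 = alpha1,
             beta = beta, beta1 = beta1)
  if (any(unlist(hp) <= 0)) {
    abort("All BCPNN hyperparameters must be > 0.",
          class = "faersignal_error_config")
  }
  hp
}

#' Signal-screening thresholds
#'
#' The standard per-method screening criteria: ROR and PRR flag when the
#' report count `a` is at least `min_a` (default 3) and the 95% CI lower
#' bound exceeds 1; BCPNN flags when `IC025 > 0`; EBGM flags when
#' `EBGM05 > 2`.
#'
#' @param min_a Minimum report count for ROR/PRR screening.
#' @param ror_ci_low_gt,prr_ci_low_gt CI lower-bound thresholds.
#' @param ic025_gt IC025 threshold.
#' @param ebgm05_gt EBGM05 threshold.
#' @return Named list of thresholds.
#' @export
signal_criteria <- function(min_a = 3, ror_ci_low_gt = 1, prr_ci_low_gt = 1,
                            ic025_gt = 0, ebgm05_gt = 2) {
  list(min_a = min_a, ror_ci_low_gt = ror_ci_low_gt,
       prr_ci_low_gt = prr_ci_low_gt, ic025_gt = ic025_gt,
       ebgm05_gt = ebgm05_gt)
}

z95 <- 1.96  # the conventional two-sided 95% normal quantile, as printed

# helper: corrected cells when any listed cell is zero
maybe_correct <- function(ct, needed) {
  if (any(unlist(ct[needed]) == 0)) {
    list(a = ct$a + 0.5, b = ct$b + 0.5, c = ct$c + 0.5, d = ct$d + 0.5,
         n = ct$n + 2, corrected = TRUE)
  } else {
    c(ct[c("a", "b", "c", "d", "n")], list(corrected = FALSE))
  }
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`; `CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell triggers the +0.5 correction for this statistic.
#'
#' @param ct A [contingency_table()].
#' @return List `ror`, `low`, `high`, `corrected`.
#' @export
compute_ror <- function(ct) {
  k <- maybe_correct(ct, c("a", "b", "c", "d"))
  ror <- (k$a * k$d) / (k$b * k$c)
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  list(ror = ror, low = exp(log(ror) - z95 * se),
       high = exp(log(ror) + z95 * se), corrected = k$corrected)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = (a/(a+b))/(c/(c+d))`;
#' `CI = exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' A zero `a` or `c` cell triggers the +0.5 correction.
#'
#' @param ct A [contingency_table()].
#' @return List `prr`, `low`, `high`, `corrected`.
#' @export
compute_prr <- function(ct) {
  k <- maybe_correct(ct, c("a", "c"))
  prr <- (k$a / (k$a + k$b)) / (k$c / (k$c + k$d))
  se <- sqrt(1 / k$a - 1 / (k$a + k$b) + 1 / k$c - 1 / (k$c + k$d))
  list(prr = prr, low = exp(log(prr) - z95 * se),
       high = exp(log(prr) + z95 * se), corrected = k$corrected)
}

#' Pearson chi-square of the 2x2 table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with `yates = TRUE`
#' the continuity correction replaces `|ad - bc|` by
#' `max(0, |ad - bc| - N/2)`. A zero margin makes the statistic undefined;
#' by convention it is reported as 0 and flagged degenerate.
#'
#' @param ct A [contingency_table()].
#' @param yates Apply Yates' continuity correction?
#' @return List `chi2`, `degenerate`.
#' @export
compute_chi2 <- function(ct, yates = FALSE) {
  m <- c(ct$a + ct$b, ct$c + ct$d, ct$a + ct$c, ct$b + ct$d)
  if (any(m == 0) || ct$n == 0) {
    return(list(chi2 = 0, degenerate = TRUE))
  }
  dev <- abs(ct$a * ct$d - ct$b * ct$c)
  if (yates) dev <- max(0, dev - ct$n / 2)
  list(chi2 = ct$n * dev^2 / prod(m), degenerate = FALSE)
}

#' BCPNN information component
#'
#' The raw information component is
#' `IC = log2( p(x,y) / (p(x) p(y)) ) = log2( aN / ((a+b)(a+c)) )`.
#' Its posterior expectation and variance under the BCPNN Dirichlet priors
#' are
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11} (N+\alpha)(N+\beta) /
#'   ((a+b+\alpha_1)(a+c+\beta_1))}, and
#' \deqn{V(IC) = \frac{1}{(\ln 2)^2}\left[
#'   \frac{N - a + \gamma - \gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
#'   \frac{N - (a+b) + \alpha - \alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
#'   \frac{N - (a+c) + \beta - \beta_1}{(a+c+\beta_1)(1+N+\beta)}\right]}
#' The screening bound is `IC025 = E(IC) - 2 sqrt(V(IC))` (exactly two
#' posterior SDs below the expectation). When a margin is zero the raw IC is
#' undefined and the result is flagged degenerate; the Bayesian quantities
#' are still returned since the priors regularize them.
#'
#' @param ct A [contingency_table()].
#' @param hp Hyperparameters from [bcpnn_priors()].
#' @return List `ic_raw`, `ic_expect`, `ic_var`, `ic025`, `degenerate`.
#' @export
compute_bcpnn <- function(ct, hp = bcpnn_priors()) {
  a <- ct$a; n <- ct$n
  m1 <- ct$a + ct$b   # target-drug margin
  m2 <- ct$a + ct$c   # event margin
  degenerate <- (m1 == 0 || m2 == 0)
  ic_raw <- if (degenerate) NA_real_ else log2(a * n / (m1 * m2))
  g <- hp$gamma11 * (n + hp$alpha) * (n + hp$beta) /
    ((m1 + hp$alpha1) * (m2 + hp$beta1))
  ic_expect <- log2(
    (a + hp$gamma11) * (n + hp$alpha) * (n + hp$beta) /
      ((n + g) * (m1 + hp$alpha1) * (m2 + hp$beta1))
  )
  ic_var <- (1 / log(2)^2) * (
    (n - a + g - hp$gamma11) / ((a + hp$gamma11) * (1 + n + g)) +
      (n - m1 + hp$alpha - hp$alpha1) / ((m1 + hp$alpha1) * (1 + n + hp$alpha)) +
      (n - m2 + hp$beta - hp$beta1) / ((m2 + hp$beta1) * (1 + n + hp$beta))
  )
  list(ic_raw = ic_raw, ic_expect = ic_expect, ic_var = ic_var,
       ic025 = ic_expect - 2 * sqrt(ic_var), degenerate = degenerate)
}

#' Large-sample limit of the BCPNN expected information component
#'
#' As the database grows (`N -> Inf`) at a fixed observed-to-expected ratio
#' `lambda = EBGM`, the posterior expectation of the information component
#' converges to `log2((a + gamma11) * lambda / (a + gamma11 * lambda))`.
#' With the default `gamma11 = 1` this ties the printed IC of a signal table
#' row to its printed case count and EBGM, which is how published IC values
#' can be checked without the underlying database margins.
#'
#' @param a Report count of the pair.
#' @param lambda Observed/expected relative reporting ratio (EBGM).
#' @param gamma11 Joint prior count, default 1.
#' @return Limiting E(IC) in bits.
#' @examples
#' ic_expected_limit(60, 92.83)   # ~5.21
#' @export
ic_expected_limit <- function(a, lambda, gamma11 = 1) {
  log2((a + gamma11) * lambda / (a + gamma11 * lambda))
}

#' Observed/expected relative reporting ratio (EBGM) with 95% CI
#'
#' `EBGM = aN/((a+b)(a+c))` — the empirical Bayes geometric mean as printed
#' in screening tables, i.e. the unshrunk observed-to-expected relative
#' reporting ratio (no gamma-mixture fitting);
#' `CI = exp(ln EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and
#' `EBGM05` is the CI lower bound. Any zero cell triggers the +0.5
#' correction.
#'
#' @param ct A [contingency_table()].
#' @return List `ebgm`, `low`, `high`, `corrected`.
#' @export
compute_ebgm <- function(ct) {
  k <- maybe_correct(ct, c("a", "b", "c", "d"))
  ebgm <- k$a * k$n / ((k$a + k$b) * (k$a + k$c))
  se <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)
  list(ebgm = ebgm, low = exp(log(ebgm) - z95 * se),
       high = exp(log(ebgm) + z95 * se), corrected = k$corrected)
}

#' All four disproportionality statistics for one 2x2 table
#'
#' Computes ROR, PRR, Pearson chi-square, the BCPNN information component
#' and EBGM with their confidence/credibility bounds, and evaluates the
#' per-method signal flags. `ic_raw` is reported as `log2(ebgm)` — the two
#' printed formulas are algebraically identical, and the identity is kept
#' exact on corrected tables by deriving one from the other.
#'
#' @param a,b,c,d Cell counts.
#' @param hp BCPNN priors ([bcpnn_priors()]).
#' @param criteria Thresholds ([signal_criteria()]).
#' @param yates Yates-correct the chi-square?
#' @return One-row tibble with columns `a`, `b`, `c`, `d`, `n`, `ror`,
#'   `ror_low`, `ror_high`, `prr`, `prr_low`, `prr_high`, `chi2`, `ic_raw`,
#'   `ic_expect`, `ic_var`, `ic025`, `ebgm`, `ebgm_low`, `ebgm_high`,
#'   `corrected`, `degenerate`, and logical flags `ror_signal`,
#'   `prr_signal`, `bcpnn_signal`, `ebgm_signal`, `all_four`.
#' @examples
#' disprop_stats(10, 20, 30, 240)
#' @export
disprop_stats <- function(a, b, c, d, hp = bcpnn_priors(),
                          criteria = signal_criteria(), yates = FALSE) {
  ct <- contingency_table(a, b, c, d)
  ror_ <- compute_ror(ct)
  prr_ <- compute_prr(ct)
  chi_ <- compute_chi2(ct, yates = yates)
  bc_ <- compute_bcpnn(ct, hp = hp)
  eb_ <- compute_ebgm(ct)
  res <- tibble(
    a = ct$a, b = ct$b, c = ct$c, d = ct$d, n = ct$n,
    ror = ror_$ror, ror_low = ror_$low, ror_high = ror_$high,
    prr = prr_$prr, prr_low = prr_$low, prr_high = prr_$high,
    chi2 = chi_$chi2,
    ic_raw = log2(eb_$ebgm),
    ic_expect = bc_$ic_expect, ic_var = bc_$ic_var, ic025 = bc_$ic025,
    ebgm = eb_$ebgm, ebgm_low = eb_$low, ebgm_high = eb_$high,
    corrected = ror_$corrected || prr_$corrected || eb_$corrected,
    degenerate = chi_$degenerate || bc_$degenerate
  )
  evaluate_signal(res, criteria)
}

#' Apply signal-screening thresholds
#'
#' Adds/overwrites the per-method flags on a result row (or tibble of rows):
#' `ror_signal` when `a >= min_a` and the ROR CI lower bound exceeds 1,
#' `prr_signal` analogously, `bcpnn_signal` when `ic025 > 0`, `ebgm_signal`
#' when `ebgm_low > 2`, and `all_four` as their conjunction.
#'
#' @param res Tibble with the statistic columns of [disprop_stats()].
#' @param criteria Thresholds ([signal_criteria()]).
#' @return `res` with the flag columns set.
#' @export
evaluate_signal <- function(res, criteria = signal_criteria()) {
  dplyr::mutate(
    res,
    ror_signal = .data$a >= criteria$min_a &
      .data$ror_low > criteria$ror_ci_low_gt,
    prr_signal = .data$a >= criteria$min_a &
      .data$prr_low > criteria$prr_ci_low_gt,
    bcpnn_signal = .data$ic025 > criteria$ic025_gt,
    ebgm_signal = .data$ebgm_low > criteria$ebgm05_gt,
    all_four = .data$ror_signal & .data$prr_signal &
      .data$bcpnn_signal & .data$ebgm_signal
  )
}

#' Disproportionality analysis of every event in the target margin
#'
#' Builds the 2x2 table for each event reported at least once with the
#' target drug and computes all statistics and flags. Rows are ordered by
#' descending EBGM — the most stringent of the four statistics, hence the
#' conventional ranking — with ties broken by event label.
#'
#' @param pc A [build_pair_counts()] result.
#' @param vocab Optional `faers_vocabulary` used to attach `soc_code`
#'   (the event's SOC code at PT level, or the SOC's own code at SOC level).
#' @param hp,criteria,yates Passed to [disprop_stats()].
#' @return A `faers_signals` tibble: `level`, `event`, `soc_code`, then the
#'   [disprop_stats()] columns, one row per event.
#' @export
analyze_all <- function(pc, vocab = NULL, hp = bcpnn_priors(),
                        criteria = signal_criteria(), yates = FALSE) {
  stopifnot(inherits(pc, "pair_counts"))
  if (pc$n_target_pairs == 0) {
    abort("No target-drug (report, event) pairs to analyze.",
          class = "faersignal_error_config")
  }
  rows <- purrr::map(pc$target$event, function(ev) {
    ct <- build_contingency(pc, ev)
    dplyr::mutate(
      disprop_stats(ct$a, ct$b, ct$c, ct$d, hp = hp, criteria = criteria,
                    yates = yates),
      event = ev, .before = 1
    )
  })
  res <- bind_rows(rows) %>%
    mutate(level = pc$level, .before = 1) %>%
    mutate(soc_code = lookup_soc_code(.data$event, pc$level, vocab),
           .after = "event") %>%
    arrange(desc(.data$ebgm), .data$event)
  class(res) <- c("faers_signals", class(res))
  res
}

lookup_soc_code <- function(event, level, vocab) {
  if (is.null(vocab)) return(rep(NA_integer_, length(event)))
  v <- as_tibble(vocab)
  if (level == "pt") {
    v$soc_code[match(event, v$pt)]
  } else {
    key <- dplyr::distinct(v, .data$soc_name, .data$soc_code)
    key$soc_code[match(event, key$soc_name)]
  }
}
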