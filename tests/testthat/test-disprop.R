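# Worked example used throughout: a=10, b=20, c=30, d=240, N=300.

test_that("the worked example reproduces all four statistics", {
  r <- disprop_stats(10, 20, 30, 240)
  expect_equal(r$ror, 4)
  expect_equal(r$ror_low, 1.7118753499, tolerance = 1e-9)
  expect_equal(r$ror_high, 9.3464749062, tolerance = 1e-9)
  expect_equal(r$prr, 3)
  expect_equal(r$prr_low, 1.6329563042, tolerance = 1e-9)
  expect_equal(r$prr_high, 5.5114763186, tolerance = 1e-9)
  expect_equal(r$chi2, 11.5384615385, tolerance = 1e-9)
  expect_equal(r$ebgm, 2.5)
  expect_equal(r$ebgm_low, 1.0699220937, tolerance = 1e-9)
  expect_equal(r$ebgm_high, 5.8415468164, tolerance = 1e-9)
  expect_equal(r$ic_raw, log2(2.5))
  expect_equal(r$ic_expect, 1.0862740803, tolerance = 1e-9)
  expect_equal(r$ic_var, 0.2869025411, tolerance = 1e-9)
  expect_equal(r$ic025, 0.0150083969, tolerance = 1e-8)
  expect_false(r$corrected)
  # Yates continuity correction: |ad-bc| - N/2 = 1650
  ry <- disprop_stats(10, 20, 30, 240, yates = TRUE)
  expect_equal(ry$chi2, 9.6955128205, tolerance = 1e-9)
})

test_that("a symmetric table is exactly null under every method", {
  r <- disprop_stats(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_equal(r$prr, 1)
  expect_equal(r$ebgm, 1)
  expect_equal(r$ic_raw, 0)
  expect_equal(r$chi2, 0)
  expect_false(any(r$ror_signal, r$prr_signal, r$ebgm_signal))
})

test_that("zero cells trigger the +0.5 correction and are flagged", {
  r <- disprop_stats(0, 10, 10, 100)
  expect_true(r$corrected)
  expect_equal(r$ror, 0.5 * 100.5 / (10.5 * 10.5), tolerance = 1e-12)
  expect_equal(r$ic_raw, log2(r$ebgm))  # identity preserved on correction
  expect_false(any(r$ror_signal, r$prr_signal, r$ebgm_signal, r$all_four))
})

test_that("degenerate margins give chi2 = 0 and a flag, not an error", {
  r <- disprop_stats(0, 0, 10, 100)
  expect_true(r$degenerate)
  expect_equal(r$chi2, 0)
  expect_true(is.finite(r$ic_expect))   # priors regularize BCPNN
})

test_that("build_contingency subtracts margins from pair counts", {
  pc <- structure(list(
    level = "pt",
    target = tibble::tibble(event = "PT_X", count = 10L),
    other = tibble::tibble(event = "PT_X", count = 30L),
    n_target_pairs = 30L, n_other_pairs = 270L
  ), class = "pair_counts")
  ct <- build_contingency(pc, "PT_X")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 10, b = 20, c = 30, d = 240))
  expect_equal(ct$n, 300)
  ct2 <- build_contingency(pc, "PT_MISSING_OTHER_SIDE")
  expect_equal(ct2$a, 0L)
  expect_equal(ct2$c, 0L)
})

test_that("signal thresholds follow the screening rules", {
  # a below the minimum count can never flag ROR/PRR
  weak <- disprop_stats(2, 100, 1000, 100000)
  expect_false(weak$ror_signal)
  # strong small-count signal flags everything
  strong <- disprop_stats(60, 1000, 600, 1000000)
  expect_true(strong$ror_signal && strong$prr_signal &&
                strong$bcpnn_signal && strong$ebgm_signal)
  expect_true(strong$all_four)
  # a = 0: all flags off
  none <- disprop_stats(0, 100, 100, 10000)
  expect_false(any(none$ror_signal, none$prr_signal, none$bcpnn_signal,
                   none$ebgm_signal, none$all_four))
  # thresholds are configurable
  crit <- signal_criteria(min_a = 100)
  expect_false(evaluate_signal(strong, crit)$ror_signal)
})

test_that("statistics agree with the literal-transcription oracle", {
  withr::with_seed(2024, {
    cols <- c("ror", "ror_low", "ror_high", "prr", "prr_low", "prr_high",
              "chi2", "ic_expect", "ic_var", "ic025",
              "ebgm", "ebgm_low", "ebgm_high")
    for (i in 1:250) {
      cells <- sample(0:500, 4, replace = TRUE)
      r <- disprop_stats(cells[1], cells[2], cells[3], cells[4])
      o <- oracle_stats(cells[1], cells[2], cells[3], cells[4])
      for (col in cols) {
        expect_equal(r[[col]], o[[col]], tolerance = 1e-10,
                     label = paste0(col, " at (",
                                    paste(cells, collapse = ","), ")"))
      }
    }
  })
})

test_that("ordering law: ror > prr > ebgm > 1 whenever ad > bc", {
  withr::with_seed(31, {
    checked <- 0
    while (checked < 200) {
      cells <- sample(1:400, 4, replace = TRUE)
      if (cells[1] * cells[4] == cells[2] * cells[3]) next
      r <- disprop_stats(cells[1], cells[2], cells[3], cells[4])
      s <- sign(cells[1] * cells[4] - cells[2] * cells[3])
      expect_equal(sign(r$ror - 1), s)
      expect_equal(sign(r$prr - 1), s)
      expect_equal(sign(r$ebgm - 1), s)
      if (s > 0) {
        expect_true(r$ror > r$prr && r$prr > r$ebgm && r$ebgm > 1)
        # Bayesian shrinkage pulls materially elevated ICs toward 0; very
        # close to independence the marginal priors can dominate instead
        if (r$ebgm >= 1.5) expect_lt(r$ic_expect, r$ic_raw)
      }
      expect_identical(r$ic_raw, log2(r$ebgm))
      checked <- checked + 1
    }
  })
})

test_that("E(IC) approaches its large-N closed form and the raw IC", {
  # scale the worked example's ratios up: cells -> cells * 10^k
  for (k in c(2, 3, 4)) {
    f <- 10^k
    r <- disprop_stats(10 * f, 20 * f, 30 * f, 240 * f)
    expect_equal(r$ic_expect, r$ic_raw, tolerance = 10^(-k) * 5)
  }
  # fixed a, growing N at constant lambda: E(IC) -> log2((a+1)L/(a+L))
  a <- 60; lambda <- 92.83
  m2 <- 1e5                                   # event margin
  n <- 1e9
  m1 <- round(a * n / (lambda * m2))          # target margin from lambda
  b <- compute_bcpnn(contingency_table(a, m1 - a, m2 - a, n - m1 - m2 + a))
  expect_equal(b$ic_expect, ic_expected_limit(a, lambda), tolerance = 1e-3)
})

test_that("ROR confidence intervals cover 1 at ~95% under independence", {
  withr::with_seed(4242, {
    p_drug <- 0.05; p_event <- 0.05; n <- 4000; reps <- 10000
    p <- c(p_drug * p_event, p_drug * (1 - p_event),
           (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
    tabs <- stats::rmultinom(reps, n, p)
    covered <- vapply(seq_len(reps), function(i) {
      ci <- compute_ror(contingency_table(tabs[1, i], tabs[2, i],
                                          tabs[3, i], tabs[4, i]))
      ci$low <= 1 && 1 <= ci$high
    }, logical(1))
    expect_gte(mean(covered), 0.93)
    expect_lte(mean(covered), 0.97)
  })
})

test_that("analyze_all orders by descending EBGM and covers the margin", {
  reac <- tibble::tibble(
    primaryid = c("1", "1", "2", "3", "3", "4", "5", "6"),
    pt = c("PT_X", "PT_Y", "PT_X", "PT_Y", "PT_Z", "PT_Z", "PT_Z", "PT_X")
  )
  pc <- build_pair_counts(reac, target_ids = c("1", "2"), level = "pt")
  res <- analyze_all(pc, vocab = tiny_vocab())
  expect_s3_class(res, "faers_signals")
  expect_setequal(res$event, c("PT_X", "PT_Y"))  # only target-margin events
  expect_equal(res$ebgm, sort(res$ebgm, decreasing = TRUE))
  expect_equal(res$soc_code[res$event == "PT_X"], 10000001L)
  expect_error(
    analyze_all(build_pair_counts(reac[0, ], character(), level = "pt")),
    class = "faersignal_error_config"
  )
})
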