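test_that("age units convert to years", {
  expect_equal(age_in_years(900, "MON"), 75)
  expect_equal(age_in_years(75, "YR"), 75)
  expect_equal(age_in_years(7.5, "DEC"), 75)
  expect_equal(age_in_years(365.25, "DY"), 1)
  expect_warning(out <- age_in_years(10, "FORTNIGHT"),
                 class = "faersignal_warning_age_unit")
  expect_true(is.na(out))
})

test_that("age bins are half-open with boundaries in the upper bin", {
  expect_equal(bin_age(75), "≥75")
  expect_equal(bin_age(74.999), "≥65,<75")
  expect_equal(bin_age(65), "≥65,<75")
  expect_equal(bin_age(17.99), "<18")
  expect_equal(bin_age(18), "≥18,<45")
  expect_equal(bin_age(NA), "Unknown")
  expect_warning(expect_equal(bin_age(-1), "Unknown"),
                 class = "faersignal_warning_negative_age")
})

test_that("time to onset subtracts dates and excludes negative gaps", {
  expect_equal(time_to_onset_days(as.Date("2020-01-10"),
                                  as.Date("2020-01-05")), 5L)
  expect_equal(bin_onset(5L), "0-7")
  expect_true(is.na(time_to_onset_days(as.Date("2020-01-05"),
                                       as.Date("2020-01-10"))))
  expect_true(is.na(time_to_onset_days(as.Date("2020-01-05"), as.Date(NA))))
  expect_equal(bin_onset(NA_integer_), "Unknown")
  expect_equal(bin_onset(c(0L, 6L, 7L, 27L, 28L, 59L, 60L, 400L)),
               c("0-7", "0-7", "7-28", "7-28", "28-60", "28-60",
                 "≥60", "≥60"))
})

test_that("percent matches the printed two-decimal half-up convention", {
  expect_equal(percent(388, 3633), 10.68)
  expect_equal(percent(299, 3633), 8.23)
  expect_equal(percent(1376, 3633), 37.88)
  expect_equal(percent(0, 10), 0)
  expect_equal(percent(1, 800), 0.13)   # 0.125 rounds up, not to even
  expect_error(percent(1, 0), class = "faersignal_error_denominator")
})

test_that("percent of a split sums to 100 within rounding slack", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(50:5000, 1)
      a <- sample(0:n, 1)
      expect_lte(abs(percent(a, n) + percent(n - a, n) - 100), 0.011)
    }
  })
})

test_that("summarize_reports maps codes and partitions the cohort", {
  cohort <- tibble::tibble(
    primaryid = c("1", "2", "3"),
    caseid = c("1", "2", "3"),
    fda_dt = as.Date(c("2020-05-01", "2021-05-01", "2021-06-01")),
    event_dt = as.Date(c("2020-03-10", NA, NA)),
    age = c(900, NA, 80),
    age_unit = c("MON", NA, "YR"),
    sex = c("F", NA, "M"),
    occp_cod = c("PH", "CN", NA),
    occr_country = c("US", "JP", NA),
    report_year = c(2020L, 2021L, 2021L),
    outcomes = list(c("DE", "HO"), character(), "DE"),
    onset_days = time_to_onset_days(
      as.Date(c("2020-03-10", NA, NA)),
      as.Date(c("2020-03-08", NA, NA))
    )
  )
  s <- summarize_reports(cohort)
  expect_equal(attr(s, "total_reports"), 3)
  get <- function(sec, lab) s$count[s$section == sec & s$label == lab]
  expect_equal(get("reporter", "Pharmacist"), 1L)
  expect_equal(get("reporter", "Unknown"), 1L)
  expect_equal(get("outcomes", "Death"), 2L)
  expect_equal(get("outcomes", "Hospitalization—initial or prolonged"), 1L)
  expect_equal(get("age", "≥75"), 2L)   # 900 months and 80 years
  expect_equal(get("sex", "Unknown"), 1L)
  expect_equal(get("onset", "0-7"), 1L)
  expect_equal(get("country", "United States"), 1L)
  expect_equal(get("country", "Not specified"), 1L)
  # partition sections sum to the total
  for (sec in c("sex", "age", "reporter", "year", "onset")) {
    expect_equal(sum(s$count[s$section == sec]), 3L)
    expect_lte(abs(sum(s$percent[s$section == sec]) - 100), 0.03)
  }
  expect_error(summarize_reports(cohort[0, ]),
               class = "faersignal_error_denominator")
})

test_that("an all-missing cohort lands entirely in Unknown bins", {
  cohort <- tibble::tibble(
    primaryid = "1", caseid = "1", fda_dt = as.Date("2020-01-01"),
    event_dt = as.Date(NA), age = NA_real_, age_unit = NA_character_,
    sex = NA_character_, occp_cod = NA_character_,
    occr_country = NA_character_, report_year = 2020L,
    outcomes = list(character()), onset_days = NA_integer_
  )
  s <- summarize_reports(cohort)
  for (sec in c("sex", "age", "reporter", "onset")) {
    expect_equal(s$count[s$section == sec & s$label == "Unknown"], 1L)
  }
})
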