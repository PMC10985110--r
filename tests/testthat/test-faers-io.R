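test_that("read_faers_table parses minimal well-formed rows of each kind", {
  demo <- read_faers_table(
    write_lines_tmp(c("primaryid$caseid$fda_dt", "1001$55$20200301")), "demo"
  )
  expect_equal(nrow(demo), 1)
  expect_equal(demo$primaryid, "1001")
  expect_equal(demo$caseid, "55")
  expect_equal(demo$fda_dt, as.Date("2020-03-01"))
  expect_equal(demo$report_year, 2020L)
  expect_true(is.na(demo$age))

  drug <- read_faers_table(
    write_lines_tmp(c("primaryid$drug_seq$drugname$role_cod",
                      "1001$1$NOURIANZ$PS")), "drug"
  )
  expect_equal(drug$role_cod, "PS")
  expect_equal(drug$drugname, "NOURIANZ")
  expect_equal(drug$drug_seq, 1L)

  reac <- read_faers_table(
    write_lines_tmp(c("primaryid$pt", "1001$Freezing phenomenon")), "reac"
  )
  expect_equal(reac$pt, "Freezing phenomenon")

  outc <- read_faers_table(
    write_lines_tmp(c("primaryid$outc_cod", "1001$DE")), "outc"
  )
  expect_equal(outc$outc_cod, "DE")

  ther <- read_faers_table(
    write_lines_tmp(c("primaryid$dsg_drug_seq$start_dt", "1001$1$202003")),
    "ther"
  )
  expect_equal(ther$start_dt, as.Date("2020-03-01"))  # partial date padded
})

test_that("malformed mandatory fields skip the row and are counted", {
  demo <- suppressWarnings(read_faers_table(
    write_lines_tmp(c("primaryid$caseid$fda_dt",
                      "1$10$2020030",      # 7-digit date -> invalid
                      "2$11$20200230",     # impossible date
                      "3$12$20200301")),
    "demo"
  ))
  expect_equal(nrow(demo), 1)
  expect_equal(attr(demo, "skipped"), 2)
  expect_equal(attr(demo, "skipped_lines"), c(1L, 2L))
  expect_warning(
    read_faers_table(
      write_lines_tmp(c("primaryid$caseid$fda_dt", "1$10$2020030")), "demo"
    ),
    class = "faersignal_warning_skipped_rows"
  )
})

test_that("headers are matched case-insensitively and extras ignored", {
  demo <- read_faers_table(
    write_lines_tmp(c("PRIMARYID$CaseId$FDA_DT$mystery_col$SEX",
                      "1$5$20210101$zzz$f")), "demo"
  )
  expect_equal(demo$sex, "F")
  expect_false("mystery_col" %in% names(demo))
})

test_that("a missing mandatory column raises a format error naming it", {
  expect_error(
    read_faers_table(write_lines_tmp(c("primaryid$fda_dt", "1$20200101")),
                     "demo"),
    regexp = "caseid", class = "faersignal_error_format"
  )
})

test_that("age without a unit is treated as missing", {
  demo <- read_faers_table(
    write_lines_tmp(c("primaryid$caseid$fda_dt$age$age_cod",
                      "1$5$20210101$75$YR",
                      "2$6$20210101$75$")), "demo"
  )
  expect_equal(demo$age, c(75, NA))
  expect_equal(demo$age_unit, c("YR", NA))
})

test_that("read_deleted_cases unions, trims and drops blanks", {
  p1 <- write_lines_tmp(c("55", "70", ""))
  p2 <- write_lines_tmp("70")
  expect_setequal(read_deleted_cases(c(p1, p2)), c("55", "70"))
  expect_equal(read_deleted_cases(write_lines_tmp("")), character())
  expect_equal(read_deleted_cases(write_lines_tmp(" 55 ")), "55")
  expect_error(read_deleted_cases("/nonexistent/deleted.txt"),
               regexp = "nonexistent", class = "faersignal_error_io")
})

test_that("write_signal_table renders two decimals and honors empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  res <- disprop_stats(10, 20, 30, 240)
  res$level <- "pt"; res$event <- "PT_X"; res$soc_code <- 10000001L
  write_signal_table(res, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  fields <- strsplit(lines[2], ",")[[1]]
  cols <- strsplit(lines[1], ",")[[1]]
  expect_equal(cols, faersignal:::signal_table_columns)
  expect_equal(fields[cols == "ror"], "4.00")
  expect_equal(fields[cols == "ror_low"], "1.71")
  expect_equal(fields[cols == "ror_high"], "9.35")

  write_signal_table(res[0, ], path)
  expect_length(readLines(path), 1)  # header only
})

test_that("generator output round-trips through the FAERS dialect", {
  syn <- generate_faers_dataset(test_config(n_reports = 300, seed = 5),
                                dir = withr::local_tempdir())
  for (kind in c("demo", "drug", "reac", "outc", "ther")) {
    reread <- read_faers_table(syn$paths[[kind]], kind)
    expect_equal(attr(reread, "skipped"), 0)
    expect_equal(as.data.frame(reread),
                 as.data.frame(syn$tables[[kind]]),
                 ignore_attr = TRUE)
  }
  expect_setequal(read_deleted_cases(syn$paths$deleted), syn$deleted)
})
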