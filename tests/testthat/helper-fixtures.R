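# Shared fixture builders: tiny in-code tables and an independent
# literal-transcription oracle for the four statistics.

demo_row <- function(primaryid, caseid, fda_dt, ...) {
  tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = as.Date(fda_dt),
    event_dt = as.Date(NA), age = NA_real_, age_unit = NA_character_,
    sex = NA_character_, occp_cod = NA_character_,
    occr_country = NA_character_,
    report_year = as.integer(format(as.Date(fda_dt), "%Y")),
    ...
  )
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tiny_vocab <- function() {
  faersignal::vocabulary(
    pt = c("PT_X", "PT_Y", "PT_Z"),
    soc_name = c("SOC One", "SOC One", "SOC Two"),
    soc_code = c(10000001, 10000001, 10000002)
  )
}

# Independent oracle: plain transcription of the four formulas plus the
# documented +0.5 policy, written scalar-by-scalar with no shared code path
# with the package internals.
oracle_stats <- function(a, b, c, d, gamma11 = 1, alpha = 2, alpha1 = 1,
                         beta = 2, beta1 = 1, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  corr_all <- min(a, b, c, d) == 0
  aa <- if (corr_all) a + 0.5 else a
  bb <- if (corr_all) b + 0.5 else b
  cc <- if (corr_all) c + 0.5 else c
  dd <- if (corr_all) d + 0.5 else d
  nn <- aa + bb + cc + dd
  ror <- (aa * dd) / (bb * cc)
  se_ror <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)

  corr_ac <- a == 0 || c == 0
  pa <- if (corr_ac) a + 0.5 else a
  pb <- if (corr_ac) b + 0.5 else b
  pc_ <- if (corr_ac) c + 0.5 else c
  pd <- if (corr_ac) d + 0.5 else d
  prr <- (pa / (pa + pb)) / (pc_ / (pc_ + pd))
  se_prr <- sqrt(1 / pa - 1 / (pa + pb) + 1 / pc_ - 1 / (pc_ + pd))

  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    chi2 <- 0
  } else {
    dev <- abs(a * d - b * c)
    if (yates) dev <- max(0, dev - n / 2)
    chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }

  g <- gamma11 * (n + alpha) * (n + beta) / ((a + b + alpha1) * (a + c + beta1))
  eic <- log((a + gamma11) * (n + alpha) * (n + beta) /
               ((n + g) * (a + b + alpha1) * (a + c + beta1))) / log(2)
  vic <- (1 / (log(2)^2)) * (
    ((n - a + g - gamma11) / ((a + gamma11) * (1 + n + g))) +
      ((n - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha))) +
      ((n - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + n + beta)))
  )

  ebgm <- aa * nn / ((aa + bb) * (aa + cc))

  list(
    ror = ror,
    ror_low = ror * exp(-1.96 * se_ror), ror_high = ror * exp(1.96 * se_ror),
    prr = prr,
    prr_low = prr * exp(-1.96 * se_prr), prr_high = prr * exp(1.96 * se_prr),
    chi2 = chi2, ic_expect = eic, ic_var = vic,
    ic025 = eic - 2 * sqrt(vic),
    ebgm = ebgm,
    ebgm_low = ebgm * exp(-1.96 * se_ror),
    ebgm_high = ebgm * exp(1.96 * se_ror)
  )
}

# small-but-complete synthetic config for fast tests
test_config <- function(n_reports = 2000, seed = 42, ...) {
  faersignal::synthetic_config(n_reports = n_reports, seed = seed, ...)
}
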