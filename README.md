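# faersignal

Disproportionality signal mining for FAERS-style spontaneous adverse-event
reports, as an R package.

## What problem this solves

Post-marketing drug safety surveillance asks: among the millions of
spontaneous adverse-event (AE) reports in a database like the FDA Adverse
Event Reporting System (FAERS), is a particular event reported with a given
drug *disproportionately often* compared with all other drugs? `faersignal`
implements the standard screening pipeline used in pharmacovigilance
studies of a single target drug:

1. **Ingestion** of FAERS quarterly-extract-style `$`-delimited ASCII tables
   (DEMO, DRUG, REAC, OUTC, THER) and deleted-case lists.
2. **Deduplication**: FAERS reports arrive in versions; per case (CASEID)
   only the version with the latest FDA receipt date is kept, ties resolved
   by the largest PRIMARYID, then deleted cases are removed.
3. **Cohort construction**: reports whose *primary suspect* drug matches the
   target drug (or any synonym) form the target cohort.
4. **Event aggregation**: MedDRA preferred terms (PTs) are normalized and
   mapped to system organ classes (SOCs); the counting unit is the unique
   (report, event) pair.
5. **Descriptive summary** of the cohort: sex, age bins, reporter
   occupation, country, report year, serious outcomes, time to onset.
6. **Disproportionality statistics** for every event's 2×2 table

   |              | target event | other events |
   |--------------|--------------|--------------|
   | target drug  | a            | b            |
   | other drugs  | c            | d            |

   with N = a+b+c+d:

   - **ROR** = ad/bc, 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
     signal when a ≥ 3 and CI lower bound > 1.
   - **PRR** = (a/(a+b))/(c/(c+d)), 95% CI
     `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`; same threshold.
   - **Pearson χ²** of the table (Yates correction optional).
   - **BCPNN information component** IC = log₂(aN/((a+b)(a+c))) with
     Bayesian posterior expectation E(IC), variance V(IC) and screening
     bound IC025 = E(IC) − 2√V(IC); signal when IC025 > 0.
   - **EBGM** = aN/((a+b)(a+c)) — the observed-to-expected relative
     reporting ratio — with the analogous 95% CI; signal when its lower
     bound EBGM05 > 2.

Because real FAERS quarters are bulky and MedDRA is licensed, the package
ships a **synthetic FAERS-like generator** (`generate_faers_dataset()`)
with known ground truth — duplicate/deleted ledgers and per-(drug, PT)
reporting-rate multipliers with a closed-form expected value — so the whole
pipeline and its statistical behavior are testable offline.

## Worked example

One 2×2 table (a = 10, b = 20, c = 30, d = 240):

```r
library(faersignal)
disprop_stats(10, 20, 30, 240)
#>       a   ror ror_low ror_high   prr  chi2 ic_expect  ic025  ebgm ebgm_low
#> 1    10     4    1.71     9.35     3  11.5      1.09 0.0150   2.5     1.07
```

The ROR of 4.0 (CI 1.71–9.35) and PRR of 3.0 both clear their thresholds;
IC025 is barely above 0; EBGM05 of 1.07 fails the > 2 rule, so `all_four`
is `FALSE`.

End to end on synthetic data:

```r
syn <- generate_faers_dataset(synthetic_config(n_reports = 20000, seed = 42))
res <- run_faers_analysis(
  syn$tables$demo, syn$tables$drug, syn$tables$reac,
  syn$tables$outc, syn$tables$ther,
  deleted = syn$deleted, vocab = syn$vocabulary,
  drug_names = syn$synonyms, quiet = TRUE
)
res
#> FAERS-style disproportionality analysis
#>   reports read: 21014 | kept: 19800 | target: 406
#>   PT-level events analyzed: 28 | all-four signals: 2
#>   SOC-level events analyzed: 8 | all-four signals: 0

head(res$signals_pt, 3)[, c("event", "a", "ror", "prr", "ic025", "ebgm", "all_four")]
#>   event                   a   ror   prr  ic025  ebgm all_four
#> 1 FREEZING PHENOMENON     6  7.32  7.27  0.673  6.47 TRUE
#> 2 COMPULSIONS             7  4.93  4.90  0.568  4.55 TRUE
#> 3 EMERGENCY CARE          3  3.48  3.47 -0.454  3.30 FALSE
```

The generator injected reporting-rate multipliers of 10 and 5 on the first
two PTs; both are recovered and flagged by all four methods. `tidy(res)`
returns the stacked PT/SOC signal tibble, `glance(res)` the one-row stage
ledger (21,014 DEMO rows → 1,014 duplicate versions and 200 deleted cases
removed → 19,800 kept, 406 in the target cohort), and `autoplot(res)` a
forest plot of RORs.

A thin CLI wrapping the same functions lives in `inst/cli/faersignal.R`
(subcommands `analyze`, `synth`, `stats`).

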