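---
title: "Methods: disproportionality signal mining on FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal mining on FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The setting

Spontaneous-reporting databases such as FAERS collect adverse-event (AE)
reports without denominators: there is no count of patients exposed, only
reports. Disproportionality analysis works around this by asking whether a
drug–event pair occupies a larger share of the target drug's reports than
the same event occupies among all other reports. Every method in this
package reduces to functions of one 2×2 table per (drug, event) pair:
`a` reports with both the target drug and the event, `b` with the drug and
other events, `c` with other drugs and the event, `d` with neither, and
`N = a + b + c + d`.

Two modelling commitments precede any statistic:

* **The report, not the mention, is the counting unit.** A report listing
  the same preferred term (PT) twice contributes one pair; at system-organ
  class (SOC) level a report with several PTs in the same SOC contributes
  one pair to that SOC. Margins are therefore unique (report, event) pairs,
  and `b = n_target_pairs − a`. A consequence worth knowing: the SOC-level
  `N` is smaller than the PT-level `N`, because SOC aggregation collapses
  pairs.
* **Cohort membership is role-based.** A report belongs to the target
  cohort when the target drug (any synonym, matched against the verbatim
  drug name or the active-ingredient field after whitespace/case
  normalization) appears with a qualifying role code — by default `PS`,
  primary suspect. Reports carrying the drug only as secondary
  suspect/concomitant/interacting count as comparator reports; `roles`
  widens the definition when a sensitivity analysis wants it.

## Cleaning rules

FAERS releases report *versions*: the same case (CASEID) reappears across
quarters under different PRIMARYIDs. `deduplicate_reports()` keeps, per
case, the version with the largest FDA receipt date, breaking ties by the
largest PRIMARYID; deletion lists are then applied case-wise. Receipt dates
must be full, valid `YYYYMMDD` values precisely because they order
versions; therapy-start and event dates may be partial (`YYYYMM`/`YYYY`)
and are padded to the first day of the period, which biases onset intervals
by at most the truncated period but keeps them usable. Identifiers are
contractually opaque strings; since "largest PRIMARYID" is meant
numerically and real ids are digit strings, ordering is numeric whenever
every id in the vector is all-digit, falling back to C-locale lexicographic
order otherwise, so the rule is total and deterministic either way. Rows
failing mandatory-field validation are skipped and counted rather than
failing the run; the skip count and line numbers travel with the table as
attributes.

Child rows (drug, reaction, outcome, therapy) of discarded versions are
dropped along with their version — only rows whose `primaryid` survives
contribute anywhere downstream.

## The four statistics

With cells `a, b, c, d` (coerced to doubles; the cross products overflow
32-bit integers at database scale):

* **ROR** `= ad/bc`, CI `exp(ln ROR ± 1.96·s)`, `s² = 1/a+1/b+1/c+1/d`.
* **PRR** `= (a/(a+b))/(c/(c+d))`, CI `exp(ln PRR ± 1.96·s)` with
  `s² = 1/a − 1/(a+b) + 1/c − 1/(c+d)`.
* **Pearson χ²** `= N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`; with the Yates flag
  `|ad−bc|` is replaced by `max(0, |ad−bc| − N/2)`. The uncorrected form is
  the default because published signal tables rarely state the variant; the
  flag exists because the choice is consequential exactly where screening
  thresholds bite (small `a`).
* **BCPNN.** The raw information component is
  `IC = log₂(aN/((a+b)(a+c)))`. Under Dirichlet priors with joint prior
  count `γ₁₁` and marginal priors `α, α₁, β, β₁`, the posterior expectation
  is

  `E(IC) = log₂[(a+γ₁₁)(N+α)(N+β) / ((N+γ)(a+b+α₁)(a+c+β₁))]`,
  `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))`,

  with the three-term posterior variance `V(IC)` in `compute_bcpnn()`'s
  documentation, and the screening bound `IC025 = E(IC) − 2√V(IC)` — the
  literal "expectation minus two posterior SDs", not 1.96.
* **EBGM** is implemented as printed in the screening-table tradition this
  package follows: the *unshrunk* observed-to-expected relative reporting
  ratio `aN/((a+b)(a+c))`, with the same log-normal CI machinery as the
  ROR, and `EBGM05` its lower bound. A full gamma-mixture MGPS (empirical
  Bayes fit with posterior quantiles) is deliberately out of scope; where a
  study reports that flavour of EBGM, values will differ at small `a`.
  One pleasant consequence of the printed formula is the exact identity
  `IC = log₂(EBGM)`, which the package enforces by construction (the two
  columns are derived from one another, also on corrected tables).

**Defaults for the priors** are the classical ones: `γ₁₁ = 1`,
`α = β = 2`, `α₁ = β₁ = 1`, centring the prior IC at independence. At
database scale the marginal priors are numerically irrelevant; `γ₁₁`
controls small-count shrinkage. All five are arguments.

**Large-sample closure.** As `N → ∞` at fixed `λ = EBGM`,
`E(IC) → log₂((a+γ₁₁)λ/(a+γ₁₁λ))`. With `γ₁₁ = 1` this ties a published
row's IC to its published `(a, EBGM)` pair with no access to the underlying
margins — the package exposes it as `ic_expected_limit()` and the
acceptance script uses it to recompute published IC values.

**Shrinkage caveat.** E(IC) < raw IC is guaranteed only for materially
elevated tables. Very close to independence (empirically, EBGM below about
1.5 on small random tables) the marginal-prior terms can push E(IC)
slightly *above* the raw IC; the property suite asserts strict shrinkage
only above that region, plus convergence `E(IC) → IC` as all cells grow.

## Numerical conventions

* **Zero cells.** A statistic whose point estimate or CI divides by a zero
  cell is recomputed on the Haldane–Anscombe table (all four cells + 0.5)
  *for that statistic only*, and the row is flagged `corrected`. ROR and
  EBGM need all four cells; PRR needs `a` and `c`. A zero margin makes χ²
  degenerate (reported as 0, flagged) while the BCPNN quantities remain
  finite because the priors regularize them.
* **Thresholds.** ROR/PRR flag at `a ≥ 3` and CI lower bound > 1; BCPNN at
  `IC025 > 0`; EBGM at `EBGM05 > 2`; `all_four` is their conjunction. All
  are arguments of `signal_criteria()`. The package reports per-method
  flags and leaves any composite "signal" labelling policy to the analyst.
* **Ranking.** Result tables sort by descending EBGM (the most conservative
  of the four point estimates, hence the conventional ranking), ties broken
  by event label so output is deterministic.
* **Rounding.** Printed percentages and CSV statistics round half *up* at
  two decimals (`round_half_up()`), matching how published tables round —
  base R's round-half-to-even disagrees on exact ties (e.g. 0.125 → 0.13,
  not 0.12).
* **1.96**, not `qnorm(0.975)`, in every CI: the formulas are implemented
  as conventionally printed, and the difference (≈2e-5 relative) is far
  below reporting precision.

## Descriptive summary conventions

Ages convert to years via `YR`/`DEC`/`MON`/`WK`/`DY`/`HR` factors (a value
without a unit is uninterpretable and treated as missing). Age bins are
half-open lower-inclusive: `[0,18) [18,45) [45,65) [65,75) [75,∞)`; onset
bins likewise `[0,7) [7,28) [28,60) [60,∞)` — published tables often print
overlapping labels ("0–7, 7–28"), so a convention must be fixed, and
lower-inclusive is it. Onset is `event_dt − start_dt` in whole days using
the *earliest therapy start of the target drug* in the report (the natural
referent when a table says "medication date"; without a drug-sequence link
the earliest start in the report is used); negative gaps are data errors
and become Unknown. The occurrence country (`occr_country`) stands in for
"reported country", a deliberate, documented choice since reporting-country
fields vary by extract vintage. Outcome percentages use the cohort size as
denominator even though a report can carry several outcome codes — the
partition property therefore holds for sex/age/reporter/year/onset but not
outcomes or countries, and the test suite checks exactly that.

## The synthetic generator

`synthetic_config()` + `generate_faers_dataset()` emulate the structural
hazards the pipeline must survive: multi-quarter receipt dates; duplicate
case versions (5% of cases by default, strictly later second versions, with
a tie mode to exercise the PRIMARYID tie-break); a deleted-case list (1%);
primary-suspect plus concomitant drug rows; ~2 PTs per report (1 +
Poisson, capped at 6, drawn with replacement and deduplicated within
report); and spontaneous-reporting missingness — 98.5% unknown sex and
age, a reporter mix dominated by pharmacists, ~99% US occurrence — so the
descriptive pipeline is exercised on realistically hollow data. Ages centre
on the early 70s (a Parkinson-disease-like cohort), mostly in years with
occasional months/decades rows to exercise unit conversion.

Signals are injected as per-(drug, PT) rate multipliers ρ: target reports
draw PTs with probabilities `p·ρ` renormalized. The closed-form recovery
target is `expected_rate = ρ/Z`, `Z = Σ pⱼρⱼ` — what ROR and PRR estimate
for rare PTs. EBGM estimates a different quantity: its event margin
includes the target drug's own reports, attenuating the estimand to
`r/(1−f+f·r)` for target share `f`; `expected_pair_rates()` returns both
columns so each estimator is checked against what it actually estimates.
Defaults inject ρ = 10, 5, 2 on three rare PTs whose baseline rates were
chosen so that a 50,000-report dataset at 2% target prevalence yields
roughly 15–20 case reports per injected PT — large enough for a stable
median across replicates, rare enough that the renormalization correction
stays within a few percent.

What the generator does *not* emulate: drug co-prescription correlation,
free-text drug-name noise beyond case/whitespace, event-term misspellings,
reporting trends over time, or duplicate reports under *different* case
ids. Passing recovery and calibration tests on this generator therefore
demonstrates the estimators and plumbing, not robustness to those
real-data pathologies.

## Validation problem sizes

The property and acceptance suites run at sizes chosen to make the checks
meaningful while staying quick: oracle equivalence against an independent
literal-transcription implementation on 1,000 random tables with cells in
[0, 500]; ROR CI coverage under independence on 10,000 multinomial tables
of size 4,000; signal recovery on 50 replicates of 50,000 reports
(medians of ROR/PRR/EBGM within 15% of the closed-form targets); null
calibration on one 50,000-report dataset with no injected effects
(< 1% of pairs may trip all four thresholds); and dedup bookkeeping against
exact generator ledgers.

## Known limitations

* No multiple-comparison adjustment — standard for screening, but the
  flags are hypotheses, not findings.
* The EBGM column is the unshrunk relative reporting ratio (see above);
  IC025/EBGM05 thresholds inherit the small-count behaviour of their
  formulas rather than of a fitted shrinkage model.
* No stratified (age/sex/year) disproportionality.
* The `$`-dialect reader does not support embedded `$` in free text, and
  real FAERS XML/SGML extracts are out of scope.
* "New AE" labelling (comparison against a drug leaflet) is an annotation
  the analyst supplies; nothing here computes it.
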