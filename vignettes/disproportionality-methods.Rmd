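---
title: "Disproportionality methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

This vignette is the package's own account of its statistical machinery:
the model behind the four disproportionality statistics, the reconstruction
oracle used to validate formula choices against published numbers, the
synthetic-data generator's design, and the numerical decisions taken where
the field's conventions leave room.

## The screening model

Spontaneous-report systems collect reports, each carrying one or more
coded adverse-event terms (MedDRA preferred terms, PTs) and one or more
drugs with role codes (primary suspect PS, secondary suspect SS,
concomitant C, interacting I). There is no exposure denominator, so
evidence of association is *disproportionality*: whether the target drug's
share of reports mentioning a term exceeds its share elsewhere in the
database.

**Counting unit.** All 2×2 tables count distinct *report–term pairs*, not
reports: `a` is the number of target-drug pairs naming the term, `a+b` the
target drug's total pairs, and `N = a+b+c+d` the database's total pairs.
Reports carry 2–3 PTs on average, so pair counts exceed report counts; in
the reference neratinib screening 1,544 deduplicated reports yield 6,488
pairs, and it is the pair margin that makes the published SOC-level counts
sum correctly. Within a report, a repeated PT counts once. At SOC level
each pair's PT is replaced by its primary SOC *without* collapsing repeats,
so SOC case counts partition the PT pair total (the alternative,
one-pair-per-report-per-SOC, is available via `pairs_to_soc(collapse =
TRUE)`).

**Deduplication.** FAERS cases accumulate versions; one row per case is
kept: highest `caseversion`, ties broken by latest receipt date, then
highest `primaryid` (the FDA's published recommendation; the precedence
chain makes the rule total and idempotent).

**Drug matching.** The target drug is found by dictionary matching
(case-insensitive, punctuation/whitespace squashed) against a synonym list
(`neratinib`, `nerlynx`, ...). The role set is a parameter; the default
`{PS}` restricts to primary-suspect mentions, which is how the reference
screening defined its cohort. Dictionary matching replaces NLP-based name
normalization: for a single target drug it is deterministic and testable.

**SOC mapping.** Full MedDRA is licensed, so the package ships a small
two-column dictionary (PT → primary SOC) covering the 48 reference signal
PTs and the synthetic vocabulary; it is user-replaceable by any file in
the same layout. Each PT maps to exactly one SOC (no multi-axiality), so
SOC counting behaves as a partition; unmapped PTs are returned with an
explicit marker and counted, never dropped.

## The four statistics

With cells `a, b, c, d` and `N` their sum:

* **ROR** `= ad/bc`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`, plus the
  *uncorrected* Pearson χ². A Yates-corrected variant sits behind
  `prr_stat(..., yates = TRUE)`.
* **IC** `= log2(aN/((a+b)(a+c)))` with variance
  `(1/ln 2)² [1/(a+1) + 1/(a+b+1) + 1/(a+c+1)]` — the large-N
  approximation of the BCPNN posterior variance (the `+1` terms keep the
  bounds finite at small `a`) — and `IC025/IC975 = IC ∓ 1.96·√V`.
* **EBGM** `= aN/((a+b)(a+c))` — the unshrunken observed/expected
  (relative reporting) ratio — with
  `EBGM05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))`.

Two of these choices deserve comment. First, `IC = log2(EBGM)` holds
identically here, and the package tests it as an invariant. Second, the
EBGM deliberately applies **no gamma–Poisson shrinkage**: the reference
screening's printed EBGM values equal the unshrunken ratio even at
`a = 3` (where a multi-item gamma-Poisson shrinker would pull the estimate
down severalfold), so the unshrunken form with a log-normal one-sided
bound is what reproduces every reference value. The inversion oracle (below)
is the evidence for the whole formula set: with these formulas, the
published interval bounds (e.g. ROR lower bounds, IC025, EBGM05) are
recovered from the published point statistics across all 48 PT rows.

**Undefined statistics.** Zero cells yield `NA` markers (ROR needs
`b·c > 0`; `a = 0` gives `IC = −∞`), not Haldane-style 0.5 corrections:
the screening only reports terms with `a ≥ 3`, so corrections would only
manufacture statistics for rows the consensus rule discards anyway. An
undefined statistic never produces a positive flag.

**Consensus rule.** Defaults: `a ≥ 3`; ROR lower bound > 1; PRR ≥ 2 with
χ² ≥ 4; IC025 > 0; EBGM05 > 2; consensus is their conjunction. All
thresholds are parameters of `signal_criteria()`. Rankings order by IC025
descending, then `a` descending, then term.

**A useful ordering.** For a given table, ROR/PRR − 1 and PRR/EBGM − 1
both carry the sign of `ad − bc`, so positively associated tables order
`ROR ≥ PRR ≥ EBGM`; this matches the reference tables and is tested as a
property. Likewise the four point estimates increase strictly in `a` only
in the screening regime where both margins are background-dominated —
outside it `aN/((a+b)(a+c))` can *decrease* in `a` — so the monotonicity
property is asserted over random tables drawn from that regime.

## The inversion oracle

The original FAERS extract cannot be redistributed, so the package
validates its formulas by *inverting* published rows: given `a`, the
margin `a+b = 6,488`, and the published PRR and χ², solve for the
background cells `c, d > 0` and recompute everything else.

The PRR equation fixes `q = c/(c+d) = (a/(a+b))/PRR`, leaving one unknown,
the background scale `s = c+d`. Along that curve the χ² is increasing in
`s` but *saturates* at `(a − (a+b)q)²/((a+b)·q·(1−q))`; the root is found
by `uniroot` on `log s`. Two numerical consequences:

* **Boundary solutions.** A published χ² can exceed the supremum by
  printed rounding alone (it happens for the gastrointestinal SOC row).
  Within 0.5% above the supremum, the oracle returns the solution at a
  large finite scale (`c+d = 1e12`) flagged `boundary = TRUE`; all derived
  statistics have converged to their large-background limits there, so
  they remain valid. Further away, it errors naming the failing equation.
* **Conditioning of the implied N.** Near the supremum, `dχ²/ds → 0`, so
  the implied database size is exquisitely sensitive to printed rounding
  — rounding PRR to two decimals can move N by an order of magnitude.
  `implied_background_size()` therefore propagates the half-ulp rounding
  box of (PRR, χ²) through the inversion and reports the interval width as
  a conditioning diagnostic. Consistency of the implied N across rows is
  only meaningful over well-conditioned rows; the acceptance check ranks
  rows by that diagnostic and uses the ten best, for which the
  `05_oracle_validation.R` script reports a coefficient of variation under
  5% around a mean N of ≈ 2.7×10⁷ pairs — a coherent single background,
  as it should be.

## Descriptive profiling

`summarize_reports()` reproduces the standard first-table profile with
explicit denominators:

* year / sex / age band / reporter / country blocks count each target
  report once (denominator: all target reports). Age bands are 18–45,
  45–65, 65–75, ≥75 (left-closed); ages under 18 or missing fall in
  "Unknown".
* the **outcome** block's denominator is reports with at least one serious
  outcome code — in the reference profile the six outcome percentages sum
  to 100 over 845 such reports, not over all 1,544 — and a report with
  several codes contributes only its most severe, with severity ordered
  DE > LT > HO > DS > RI > OT (death worst). The reference screening
  does not state its collapse rule; this one is monotone and reproduces
  the reference percentages.
* **time to onset** is event date minus the earliest precise therapy start
  date, binned half-open: `[0,7)`, `[7,28)`, `[28,60)`, `[60,∞)` (so
  exactly 7 days is "7–28"; the published bin labels are ambiguous at the
  edges). Negative differences and imprecise dates (YYYYMM / YYYY, parsed
  with day/month imputed but flagged) are "Unknown". Denominator: all
  target reports.

Percentages are rounded to two decimals and tested to round-trip from
their counts within 0.01.

## Time scans

`ic_over_time()` rebuilds the term's 2×2 table per calendar year from all
pairs accumulated up to that year (report year = receipt year, falling
back to event year) and recomputes IC with both 1.96·√V bounds. The
cumulative mode is the default because credibility intervals then narrow
monotonically as data accumulate, which is the diagnostic the trajectory
is read for; a per-year mode (`cumulative = FALSE`) is available. A year
is flagged when IC025 > 0, i.e. when 0 is excluded from the interval.

## The synthetic generator

`sim_config()` defaults define the study conditions the test-suite runs
under; they emulate a FAERS-scale screening of a rare target drug:

| parameter | default | rationale |
|---|---|---|
| `quarters` | 2017Q3–2023Q4 | the reference observation window (26 quarters) |
| `n_background_pts` | 200 | enough vocabulary for stable background margins |
| `background_pt_weights` | Zipf (rank⁻¹) | event frequencies in SRS data are heavy-tailed |
| `pts_per_report_mean` | 2.5 | pair totals ≈ 2–3× report totals, as in the reference data (6,488 pairs / 1,544 reports) |
| `drug_exposure_prob` | 0.01 | the target drug is rare in the stream |
| `duplicate_rate` | 0.05 | a visible but minority duplicate load to exercise dedup |
| `missing_age_rate`, `missing_sex_rate` | 0.972 / 0.966 | the reference profile's missingness (>90% unknown) |
| `country_mix`, `reporter_mix` | US-dominated; pharmacist-led | the reference profile's mixes |
| `serious_prob`, `outcome_mix` | 0.547; HO/DE/LT/DS/RI/OT as in the reference profile | outcome-block denominators behave like the reference data |
| `missing_ther_rate` | 0.72 | the reference time-to-onset "Unknown" share |
| `tto_dist` | mixture over <7 / 7–28 / 28–60 / ≥60 days (0.52/0.21/0.11/0.16) | the reference bin proportions among resolvable onsets |

**Planting model.** Exposed reports draw PTs with weights `w_j·rrr_j`
renormalized; unexposed with `w_j`. Renormalization is simple and monotone
in `rrr`, but it *attenuates* large planted ratios (raising one PT's
weight lowers every other's, and the planted PT's own share saturates), so
recovery is approximate and all recovery tests use intervals, not
equalities: a planted `rrr = 8` on a mid-rank PT is recovered with EBGM
around 6–7. PTs within a report are distinct: slots are drawn with
replacement and any report with a collision is redrawn wholesale, which
converges in a handful of rounds at these weights.

**Determinism.** A single seed drives the whole generation via
`withr::with_seed`, so the same configuration is byte-identical and the
caller's RNG stream is untouched. Duplicates are emitted as the same
`caseid` with `caseversion` 2, a later receipt date and copied child rows.

**What it does not emulate** — and therefore what passing tests do not
show about real data: reporting-volume dynamics over time (no Weber
effect, uniform quarters), drug–drug interaction structure, correlated PT
co-occurrence (PTs are drawn independently within a report), real-world
name misspellings beyond synonym/case/punctuation variation, LLT-level
coding, and non-random missingness.

## Problem sizes and runtimes

The calibration and recovery checks run the full pipeline on 20 replicate
databases of 200,000 reports each (null and planted arms), the scale at
which the planted PT's expected `a` comfortably exceeds 20; smaller unit
tests use 20,000–60,000 reports. The whole suite completes in a few
minutes on one core. Null calibration at that scale flags essentially no
consensus false positives (the acceptance bound is 2% of PTs with
`a ≥ 3`); planted `rrr = 8` signals are recovered by all four algorithms
in every replicate.

## Known limitations

* The EBGM is intentionally the unshrunken relative reporting ratio (see
  above); a true multi-item gamma–Poisson shrinker is out of scope and
  would *not* reproduce the reference values.
* No stratified (age/sex) disproportionality and no multiplicity
  adjustment — matching the screening being reproduced, which applies
  none.
* SOC-level inversion is limited by printed rounding: rows whose χ² sits
  beyond its supremum at printed precision cannot be inverted exactly and
  are handled as boundary cases or reported as infeasible.
* The toy dictionary is a stand-in; real analyses should supply a licensed
  MedDRA export.
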