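# faersignal

Disproportionality signal detection for spontaneous adverse-event report
databases, built around the post-marketing safety profile of **neratinib**
(an irreversible pan-HER tyrosine-kinase inhibitor used in HER2-positive
breast cancer) in FAERS-style data.

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) have no denominator of exposed patients, so drug–event associations
are screened by *disproportionality*: for each adverse-event term, a 2×2
table is formed over report–event pairs,

|                    | event of interest | other events |
|--------------------|-------------------|--------------|
| target drug        | a                 | b            |
| all other drugs    | c                 | d            |

and the observed reporting frequency of the pair is compared with its
expectation under independence. The package computes four standard
statistics for every MedDRA preferred term (PT) and system organ class
(SOC):

- **ROR** = ad/bc with the log-normal 95% CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d));
- **PRR** = [a/(a+b)]/[c/(c+d)] with its 95% CI and the uncorrected
  Pearson χ²;
- **IC** (BCPNN information component) = log₂(aN/((a+b)(a+c))), with 95%
  credibility bounds from the large-N approximation of the BCPNN posterior
  variance;
- **EBGM** = aN/((a+b)(a+c)) with the one-sided 5% lower bound EBGM05
  (z = 1.64 on the log scale).

A term is a **consensus signal** when it meets all four positivity rules
simultaneously (a ≥ 3; ROR lower bound > 1; PRR ≥ 2 with χ² ≥ 4;
IC025 > 0; EBGM05 > 2).

The package is aimed at pharmacovigilance analysts and methodologists who
want a tested, fully scripted version of this workflow: FAERS-style
quarterly table ingestion, case-version deduplication, drug-name synonym
matching, PT→SOC mapping, the four algorithms with interval estimates,
descriptive report profiling, cumulative information-component time scans,
and a synthetic report-database generator with *planted* association
strengths so every stage can be validated against known ground truth. A
numeric **inversion oracle** reconstructs 2×2 tables from published
statistics (PRR and χ² given the target margin) to validate the formula
choices against a published neratinib screening without access to the
original extract.

## Worked example

Simulate a 50,000-report database with one planted eight-fold association,
deduplicate, and screen:

```r
library(faersignal)
library(data.table)

out <- generate_database(sim_config(n_reports = 50000, seed = 42,
        planted_signals = c("synthetic pt 020" = 8)))
db  <- deduplicate(out$db)
ids <- match_target_drug(db, neratinib_synonyms())
pairs <- drug_event_pairs(db)
res <- disproportionality(build_tables(pairs[primaryid %in% ids], pairs))
rank_by_ic025(res[consensus == TRUE])[, .(term, a, ror = round(ror, 2),
  prr = round(prr, 2), ic025 = round(ic025, 2), ebgm05 = round(ebgm05, 2))]
```

```
               term     a   ror   prr ic025 ebgm05
1: synthetic pt 020    77  7.01  6.66  2.31   5.15
```

The planted PT — and nothing else — passes the four-algorithm consensus:
77 of the 529 target-drug report–event pairs involve it, its reporting odds
ratio is 7.0, and the lower credibility/confidence bounds (IC025 2.31,
EBGM05 5.15) sit well above their thresholds. The point estimates recover
the planted strength only approximately (weight renormalization in the
generator attenuates large planted ratios; see the methods vignette).

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

1. `01_simulate.R` — generate the quarterly file sets + ground truth;
2. `02_signals.R` — end-to-end pipeline, consensus signals vs planted truth;
3. `03_descriptives.R` — the descriptive report profile;
4. `04_timescan.R` — cumulative IC trajectories for a planted and a null PT;
5. `05_oracle_validation.R` — inversion-oracle reproduction of the
   published neratinib PT/SOC statistics and the implied background size.

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

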