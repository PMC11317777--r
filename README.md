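# faerspv

Pharmacovigilance signal detection on FAERS-style adverse-event reports.

Spontaneous reporting databases such as the FDA Adverse Event Reporting
System (FAERS) collect suspected adverse drug reactions without an exposure
denominator, so drug safety questions are answered by *disproportionality*:
is an event reported more often for one drug than for all other drugs in
the same database? `faerspv` implements that workflow end to end for the
FAERS quarterly ASCII format, configured by default as a pediatric
(< 18 years) screen of three tetracyclines — doxycycline, minocycline and
tigecycline. It is aimed at pharmacoepidemiologists and drug-safety
analysts who want a tested, reproducible pipeline rather than ad-hoc
spreadsheet arithmetic.

## What it does

- **IO** — reads/writes the six "$"-delimited tables (DEMO, DRUG, REAC,
  OUTC, INDI, THER) with partial-date precision tracking, per-record skip
  accounting, and referential-integrity validation.
- **Deduplication** — the FDA case rule: per CASEID keep the latest FDA_DT,
  ties broken by the numerically higher PRIMARYID.
- **Cohort** — a logged inclusion funnel: study window, age in `[0, 18)`
  (unit codes DEC/YR/MON/WK/DY/HR converted by fixed constants), target
  drug matched through an exact synonym dictionary in a suspect role
  (PS/SS), at least one reaction PT.
- **Signals** — for each (drug, PT), the 2×2 table over case–PT units and
  the reporting odds ratio

  `ROR = (a/c)/(b/d) = ad/bc`,
  `95% CI = exp(ln ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d))`,

  flagged significant when `a ≥ 3` and the CI lower bound exceeds 1;
  top-k tables with a stop-list of drug-unrelated PTs, and per-SOC
  summaries through a flat PT→primary-SOC map.
- **Descriptives** — baseline tables with most-severe-outcome selection
  (DE > LT > HO > DS > CA > RI > OT), fatal-case drill-downs, subgroup
  tables (intracranial hypertension, suicidality, DRESS, thyroid
  dysfunction, dental staining under 8) with time-to-onset medians and
  IQRs, and co-occurrence profiles.
- **Synthetic data** — a generator emulating the FAERS relational structure
  with duplicate clusters and drug–event associations injected at specified
  odds ratios, plus a deterministic reference fixture.

## Worked example

```r
library(faerspv)

db <- make_reference_fixture()          # deterministic reference database
db$demo <- deduplicate_reports(db$demo)
cohort <- build_cohort(db)

cohort$per_drug
#> # A tibble: 3 × 3
#>   drug        n_cases n_drug_event
#>   <chr>         <int>        <int>
#> 1 DOXYCYCLINE     782          796
#> 2 MINOCYCLINE     981         1142
#> 3 TIGECYCLINE     140          165
```

782/981/140 are the per-drug case counts after deduplication and the
pediatric funnel; `n_drug_event` counts distinct (case, PT) units. The
under-8 dental-staining analysis restricts both cohort and comparator to
children under 8 before recomputing the signal:

```r
under8_analysis(cohort)$signals[, c("drug", "pt", "n", "ror", "ci_low", "ci_high")]
#>   drug        pt                       n   ror  ci_low ci_high
#> 1 DOXYCYCLINE tooth discolouration     7  30.3    6.22    148.
```

Seven staining reports among 103 under-8 doxycycline cases against two
comparator reports give an ROR of 30.3 with a CI excluding 1 — a signal
under the `n ≥ 3`, CI-lower-bound > 1 rule. A full artifact set (funnel,
baseline, signal tables, subgroups, co-occurrence, under-8, manifest with
content hashes) comes from one call:

```r
cfg <- run_config(data_dir = "fixture_dir", out_dir = "artifacts")
run_pipeline(cfg)
```

or from the shell via the installed `faerspv` script
(`faerspv run-all --data <dir> --out <dir>`, plus `synth`, `validate`,
`dedup`, `cohort`, `signals`, `baseline`, `subgroup`, `cooccur`, `under8`).

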