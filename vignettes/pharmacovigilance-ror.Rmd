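---
title: "Disproportionality screening of FAERS-style reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of FAERS-style reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
post-marketing reports of suspected drug reactions. They have no
denominator — we observe who reported, not who was exposed — so incidence is
not estimable. What *is* estimable is disproportionality: whether an event
is reported more often for one drug than for all other drugs in the same
database. `faerspv` implements that analysis end to end for FAERS-style
quarterly ASCII data, with a pediatric tetracycline screen (doxycycline,
minocycline, tigecycline, patients under 18) as its default configuration.

## Data model and deduplication

A report lives in six "$"-delimited tables: DEMO (demographics, dates),
DRUG (verbatim drug names with role codes), REAC (MedDRA preferred terms,
PTs), OUTC (outcome codes), INDI (indications), THER (therapy start dates).
One *case* may be reported several times as follow-ups arrive. We keep, per
CASEID, the report with the latest FDA receipt date, breaking ties by the
numerically higher PRIMARYID — the FDA's published rule. The operation is a
pure argmax, so it is idempotent and independent of row order; both
properties are tested, as is agreement with a brute-force scan on planted
duplicate clusters.

Partial dates are kept with an explicit precision flag (year/month/day).
The receipt date used for windowing and ordering must be a full calendar
date; records violating that are counted and skipped, never silently
dropped: each parsed file reconciles `lines = records + skips`.

## Cohort construction

The inclusion funnel applies, in order: receipt date within the study
window (2005-01-01 to 2023-09-30 by default); age convertible to years and
within `[0, 18)` — decades, years, months, weeks, days and hours convert by
fixed constants (52.18 weeks, 365.25 days, 8766 hours per year; the choice
is immaterial at the 18-year boundary but must be deterministic); at least
one target drug, matched by exact synonym lookup after case/whitespace
normalization (no fuzzy matching — a misspelled name maps to "other"); and
at least one reaction PT. Reports with missing age are excluded: "under 18"
cannot be affirmed. Every stage's count is a first-class output.

A case with two target suspects (e.g. doxycycline + minocycline) counts in
both drugs' tallies, appears in subgroup tables only in a combined row, and
is excluded from both drugs' comparators.

## The reporting odds ratio

The analysis unit is a distinct (case, PT) pair after deduplication. For
drug $g$ and PT $p$:

|            | PT $p$ | other PTs |
|------------|--------|-----------|
| cases on $g$ | $a$  | $b$       |
| comparator | $c$    | $d$       |

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc}, \qquad
95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm z
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

with $z = 1.96$. A pair is a *signal* when $a \ge 3$ and the CI lower bound
exceeds 1. Both thresholds are configurable (`signal_criteria()`). No
multiple-testing adjustment is applied — the screen is hypothesis
generating, and the criteria are deliberately the plain published rule.

Degenerate cells follow fixed conventions: $a = 0$ reports ROR 0 with no
interval; $a > 0$ with $b = 0$ or $c = 0$ reports an infinite sentinel; the
interval is undefined whenever any cell is 0. No continuity correction is
applied by default — published single-report rows are consistent with the
uncorrected formula — but a Haldane–Anscombe 0.5 correction is available by
flag for users who prefer finite estimates everywhere. Display rounding is
two decimals, ties away from zero; internal values keep full precision.

**Choice of comparator.** The published procedure never states whether $c$
and $d$ come from pediatric reports or all reports. The default here is the
pediatric in-window population across all drugs (the study frame), with
`background_scope = "all"` available. The target drug's own units are
removed from the comparator, so a case never competes with itself.

## Descriptive surfaces

*Baseline tables* select each case's most severe outcome under the fixed
ranking death > life-threatening > hospitalization > disability >
congenital anomaly > required intervention > other; an empty outcome set is
"Unknown". Receipt years bin into 3-year periods anchored at the window
start, the final partial bin labelled with the quarters it covers. Age
bands are 0–7 (age < 8) and 8–18 (8 ≤ age < 18) so the bands partition the
cohort. *Quartiles* everywhere use linear interpolation between order
statistics inclusive of the extremes (R's `quantile` type 7); published
tables never state their method, and integer medians do not discriminate,
so determinism drove the choice. *Time to onset* is the day difference
between the event date and the earliest therapy start for the drug,
defined only when both dates carry day precision; negative gaps (data
errors) are treated as missing and counted. *Co-occurrence profiles* report,
for each PT occurring alongside an index PT, the share of the drug's cases
with that PT that also have the index PT — 100% means the PT never occurs
without it. Percentages are rounded half-up to two decimals; note one
published drill-down prints 81.81% for 27/33 where half-up gives 81.82.

## The synthetic generator

Real FAERS data cannot ship with a package, so every stage is exercised on
generated data (`generate_database()`) plus one fully deterministic fixture
(`make_reference_fixture()`).

The generator emulates the *relational* structure — duplicate report
versions sharing a case id with non-decreasing receipt dates and occasional
ties (both branches of the dedup rule), age-unit codes with months used
under age two, multi-drug reports with suspect/concomitant roles, partial
therapy and event dates — and the *statistical* structure: each PT is
included in a case independently with its background frequency $\pi_0$, and
a planted association (drug $g$, PT $p$, odds ratio $\omega$) replaces
$\pi_0$ for exposed cases by $\pi_1$ with
$\pi_1/(1-\pi_1) = \omega\,\pi_0/(1-\pi_0)$. Injecting on the odds scale
makes the planted quantity the same estimand the screen estimates. Because
the 2×2 table counts drug–event units rather than cases, the screen's
expectation is $\frac{\pi_1/(S-\pi_1)}{\pi_0/(S-\pi_0)}$ with $S$ the mean
PTs per case, which approaches $\omega$ when $\pi_0 \ll S$; recovery is
therefore evaluated where it is well-posed — rare PTs
($\pi_0 \approx 0.015$) with enough exposed cases for $a \ge 10$.

Defaults mirror the study conditions: window 2005–2023, three tetracycline
targets inside a background of common drugs, pediatric-heavy ages with
drug-specific medians (≈14, ≈15.5 and ≈7 years) plus a 20% adult fraction
to exercise the age filter, drug-specific sex ratios, ≈3.4 PTs per case,
15% duplicate cases with up to 3 versions and 0–180-day receipt jitter.
One RNG sub-stream per component keeps generation reproducible and stable
under extension; identical configurations yield byte-identical files.

What the generator does *not* emulate — real FAERS marginal distributions,
co-prescription structure, reporting-lag dynamics, spelling noise beyond
the synonym dictionary — bounds what passing tests show: they validate the
procedure (parsing, dedup rule, cell construction, formulas, rounding,
determinism) and its statistical calibration under a clean reporting model,
not performance on the raw corpus.

## Validation summary

The test-suite checks, among others:

- parsing totality and round-trip identity of the "$" dialect;
- dedup = brute-force argmax, idempotent, permutation-invariant, at $10^5$
  reports in seconds;
- ROR = cross-product ratio to $10^{-12}$; Wald CI against a hand-evaluated
  reference on the (10, 90, 100, 9900) table and an independent logistic
  (binomial GLM) fit;
- cell conservation $a+b+c+d = $ total units for every screened pair;
- null calibration: with no planted signals, across ≈7,400 screened pairs
  the share with CI lower bound above 1 is near the one-sided nominal 2.5%
  (the Wald interval's small-cell anti-conservatism leaves it slightly
  above; the accepted band is 0.5–4.5%);
- recovery: a planted $\omega = 5$ signal is detected in ≥95% of 50 seeds
  with median estimate within ±25% of 5 on the log scale;
- end-to-end determinism of the full artifact set on the fixture.

Problem sizes (6,000-case null databases, 3,000-case recovery databases,
50 seeds) were chosen to keep Monte-Carlo error small while the whole suite
runs in about a minute on one CPU.

## Worked example

```{r example, eval = FALSE}
db <- make_reference_fixture()
db$demo <- deduplicate_reports(db$demo)
cohort <- build_cohort(db)
cohort$per_drug
#>   drug        n_cases n_drug_event
#> 1 DOXYCYCLINE     782          796
#> 2 MINOCYCLINE     981         1142
#> 3 TIGECYCLINE     140          165

signals <- detect_signals(cohort)
top_k_signals(signals, "MINOCYCLINE", k = 5)
under8_analysis(cohort)$signals[, c("drug", "pt", "n", "ror", "ci_low", "ci_high")]
```

## Known limitations

Spontaneous-report caveats apply in full: no causality, reporting bias,
no incidence. The Wald interval is anti-conservative for very small cells;
the report-count criterion ($a \ge 3$) exists precisely to keep the
smallest cells out of signal lists, and the Haldane flag offers a
robustness check. The PT→SOC map is a flat single-primary-SOC stand-in for
the licensed MedDRA hierarchy, and the drug dictionary is exact-match only.
The country field is a single configurable column; sources differ on
whether reporter or occurrence country is printed in baseline tables.
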