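---
title: "Disproportionality signal detection on FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spontaneous adverse-event reporting systems such as FAERS collect
case reports of suspected drug harms without any denominator of drug use.
The standard way to mine them is *disproportionality analysis*: for a drug
of interest and each adverse event (a MedDRA Preferred Term, PT, or its
System Organ Class, SOC), classify every report in the database into the
2×2 table

|                | event | no event |
|----------------|-------|----------|
| **target drug**    | a     | b        |
| **all other drugs**| c     | d        |

and ask whether `a` is larger than independence of rows and columns would
predict. `faerspv` implements the full path from raw quarterly ASCII
tables to ranked signal tables: reading and validating the DEMO / DRUG /
REAC / THER / OUTC tables, case-version deduplication, primary-suspect
screening by drug-name keywords, the four statistics below, subgroup
(sex and age) analyses, sex-contrast volcano data, and time-to-onset
binning. A seeded synthetic generator with planted disproportionality
makes every stage testable without access to the real database.

# The four algorithms

All four statistics are computed by `disprop()` from the same table; the
counting unit everywhere is the *(report, event) pair*: a report counts
once toward `a` if any of its distinct PTs satisfies the event, so
`a + b` is the number of target-drug reports in the universe.

* **ROR** (reporting odds ratio): `ad/bc` with the Woolf interval
  `exp(log ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`.
  Positive when `a ≥ 3` and the lower bound exceeds 1.
* **PRR** (proportional reporting ratio): `(a/(a+b)) / (c/(c+d))` with the
  uncorrected chi-squared
  `N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`.
  Positive when `a ≥ 3`, `PRR ≥ 2` and `χ² ≥ 4` (both inclusive).
* **BCPNN information component**: the point IC is
  `log2(aN / ((a+b)(a+c)))`; its posterior expectation and variance use a
  Dirichlet/Beta prior with `γ11 = 1`, `α1 = β1 = 1`, `α = β = 2` and the
  derived joint parameter
  `γ = γ11 (N+α)(N+β) / ((a+b+α1)(a+c+β1))`, which centres the prior IC
  at zero. `IC025 = E(IC) − 2·sqrt(V(IC))`; positive when `a ≥ 3` and
  `IC025 > 0` (strict).
* **EBGM**: implemented in the closed observed/expected form
  `aN / ((a+b)(a+c))` — identically `2^IC` — with
  `EBGM05 = exp(log EBGM − 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`; positive
  when `a > 0` and `EBGM05 > 2` (strict). This is a deliberate design
  choice: the closed form is the simplification consistent with IC/EBGM
  pairs seen in published signal tables, and the full DuMouchel
  gamma-Poisson mixture MLE is out of scope. Only the minus branch of the
  exponent is used for EBGM05, since "05" denotes a lower bound.

A *positive signal* requires all four flags simultaneously — a
deliberately conservative conjunction that trades sensitivity for a very
low false-positive rate (the package's own null calibration below
measures it at under 5%, usually 0%).

```{r, eval = FALSE}
library(faerspv)
disprop(30, 70, 300, 9700)
```

## Numerical choices

* **Zero cells.** When `a > 0` but `b`, `c` or `d` is zero, all four
  statistics are computed on a Haldane-corrected table (+0.5 on every
  cell) and marked `corrected`; `a = 0` leaves the statistics undefined
  with every flag false. Eligibility gates always use the uncorrected `a`.
* **Thresholds.** `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4` are inclusive; `IC025 > 0`
  and `EBGM05 > 2` are strict, because they bound open criteria.
* **No continuity correction** in χ² by default (a `yates` switch
  exists), and no multiplicity adjustment anywhere — signal criteria are
  screening rules, not hypothesis tests; this is documented as a
  limitation.
* **Ranking ties** break by event name in a locale-independent (radix)
  order, so tables are byte-reproducible.

# Case processing

* **Deduplication** follows the FDA-recommended rule: within each
  `caseid` keep the version with the largest `fda_dt`, ties resolved by
  the largest `primaryid`. Partial dates are compared on the numeric
  `yyyymmdd` scale with missing components padded by zeros, giving a
  deterministic total order in which lower-precision dates sort earlier.
* **Primary-suspect screening** is case-insensitive, accent-folded
  substring matching of a keyword list against the verbatim drug name
  *and* the active-ingredient field (searching both is a package
  decision; it can only add reports, never remove them). Only role code
  `PS` qualifies a report.
* **Age bands** are half-open: `<18`, `18–65` (65 excluded), `≥65`.
  Published tables print the bands as "18–65" and "≥65", which overlap at
  exactly 65; assigning 65.0 to `≥65` makes the bands a partition.
* **PT → SOC mapping** is a required user input (two-column table),
  because MedDRA is licensed and cannot ship with the package; the
  bundled map is synthetic, covers only the generator's vocabulary, and
  is labelled accordingly.
* **Ages** convert to years via DEC×10, MON÷12, WK÷52.1775, DY÷365.25,
  HR÷8766 (mean Gregorian year).

# Time to onset and subgroup analyses

Time to onset is `event_dt − therapy_start` in whole days, where
`therapy_start` is the earliest full-precision start date among a
report's primary-suspect drugs. Partial dates are excluded, never
imputed, and negative differences are dropped and tallied, matching the
convention of excluding reports that lack onset information. Bins are
30-day intervals to 180 days, then 181–360, then >360, upper-edge
inclusive.

Stratified detection (`stratify()`) restricts *both* margins of every
table to the stratum, so a stratum that covers the whole universe
reproduces the unstratified result exactly. The sex-contrast volcano
plot compares male versus female *within target-drug reports*: per event,
`x = log3` of the male/female odds ratio (base 3 kept configurable — it
is unusual, but it is the published convention this package mirrors) and
`y = −log10 p` from a two-sided Fisher exact test (well-defined at small
counts; a χ² option exists). The alternative contrast
(drug-vs-background within each sex) is deliberately not the default;
the male-vs-female framing directly matches "more likely to occur in
male patients".

# The synthetic generator

`synth_faers()` emits the five quarterly tables in the exact `$` dialect
plus a truth table of planted pairs. Each report draws one
primary-suspect drug from a marginal distribution and each background PT
independently with probability `p`; a planted `(drug, pt, rr)` raises
that probability to `min(1, rr·p)` for that drug's reports. Reports that
would carry no PT are redrawn, so observed rates are conditioned on
"at least one event". This resampling inflates every per-PT rate by the
same factor `1/P(≥1 event)` in both arms, so ratio statistics are only
mildly biased (upward for the ROR, downward for the PRR, both well
inside sampling noise at the default scale); the bias is shared by any
case-only database and is quantified in the recovery tests.

Default study conditions (chosen once, as realistic for this class of
data): 50,000 cases; the target drug holds 1% of reports — a target
drug's small share of the database is what makes EBGM ≈ rate ratio,
since EBGM = RR/(w·RR + 1 − w) at target share `w`; ~40 background PTs
with planted-pair PTs at `p = 0.01`; planted rate ratios 10, 5, 2; 10%
duplicate case versions; missingness patterned on published completeness
figures (7.86% sex, 25.51% age, ~72% unusable onset dates); a 62.8%
female share among known-sex reports; an age mix of 6.0 / 63.4 / 30.6%
across the three bands among known ages; and an onset distribution
concentrated in the first month (86.10% in days 0–30, 2.22% in 31–60,
0.53% in 121–150, 2.60% in 181–360, 5.75% beyond 360; the three bins
without a published share split the remainder as 1.20 / 0.80 / 0.80%).
Duplicate versions perturb only `primaryid`/`fda_dt` so they isolate the
deduplication rule. All randomness derives from one root seed;
generation is byte-deterministic.

What the generator does **not** emulate: drug co-prescription structure,
free-text name noise beyond what synonym matching exercises, reporter
country realism, event–event correlation within a report, and secular
trends. Passing recovery tests therefore show that the statistics and
plumbing are correct under a clean null with planted effects — not that
the pipeline is robust to every pathology of real spontaneous-report
data.

# Problem sizes used in the test suite

Unit tests run at a few hundred to a few thousand synthetic cases;
parameter-recovery and null-calibration checks run at the full default
50,000 cases, where the planted rate ratios are recovered by ROR, PRR
and EBGM within three delta-method standard errors on the log scale and
the four-criterion conjunction flags no null pair in practice. These
sizes were chosen as the smallest that leave comfortable statistical
margins for the planted effects.

# Known limitations

* Signal criteria are screening heuristics on reporting data; nothing
  here estimates incidence or supports causal claims.
* The EBGM is the closed-form simplification, not the gamma-Poisson
  mixture posterior; for very sparse tables the true MGPS shrinks
  harder.
* Outcome percentages use outcome *entries* as the denominator (a report
  may carry several outcome codes) — the only convention under which
  published outcome tables reconcile; country percentages use reports
  with a known country, and the denominator is always reported
  alongside.
* Embedded `$` in free text would split fields: the dialect has no
  quoting, by convention.
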