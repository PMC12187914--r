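# faerspv

Pharmacovigilance signal detection for FAERS-style spontaneous
adverse-event report data, in R.

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect case reports of suspected drug harms with no
denominator of drug use. The standard screening technique is
**disproportionality analysis**: for a target drug and each adverse event
(MedDRA Preferred Term or System Organ Class), every report in the
database falls into a 2×2 table — `a` target-drug reports with the event,
`b` without, `c`/`d` the same for all other drugs — and the question is
whether `a` exceeds what row/column independence predicts.

`faerspv` implements the full path from raw quarterly ASCII extracts to
ranked signal tables:

* **I/O** — reads and validates the `$`-delimited DEMO / DRUG / REAC /
  THER / OUTC tables (header-name column resolution, record-level reject
  collection, partial-precision date parsing).
* **Case processing** — FDA-rule deduplication (largest `fda_dt`, then
  largest `primaryid`, per `caseid`), primary-suspect screening by
  accent-folded keyword matching, age conversion and banding, PT→SOC
  mapping against a user-supplied table.
* **Statistics** (`disprop()`) — the four standard algorithms with their
  positivity criteria:
  * ROR `= ad/bc`, positive when `a ≥ 3` and the Woolf 95% lower bound > 1;
  * PRR `= (a/(a+b))/(c/(c+d))` with χ², positive when `a ≥ 3`,
    `PRR ≥ 2`, `χ² ≥ 4`;
  * BCPNN information component `IC = log2(aN/((a+b)(a+c)))` with
    posterior `E(IC)`, `V(IC)` and `IC025 = E(IC) − 2√V(IC)`, positive
    when `a ≥ 3` and `IC025 > 0`;
  * EBGM `= aN/((a+b)(a+c))` (= `2^IC`) with lower bound `EBGM05`,
    positive when `a > 0` and `EBGM05 > 2`.
  A *positive signal* is the conjunction of all four.
* **Subgroups** — sex- and age-stratified detection, male-vs-female
  volcano data (`x = log3 OR`, `y = −log10` Fisher p), time-to-onset
  binning and distribution.
* **Synthetic data** — a seeded FAERS-dialect generator with planted
  reporting-rate ratios, duplicate case versions and configurable
  missingness, plus closed-form truth tables, so the whole pipeline is
  testable without any download.

## Worked example

Generate a synthetic universe of 20,000 reports with three planted
signals on the target drug (rate ratios 10, 5, 2), assemble case
reports, and detect PT-level signals:

```r
library(faerspv)

cfg   <- synth_config(n_cases = 20000, seed = 7)
syn   <- synth_faers(cfg)
cases <- build_case_reports(syn, lorazepam_synonyms())
cases
#> <faers_cases> 20000 reports (203 target-drug)
#>   flow: 22028 raw DEMO rows -> 20000 after dedup -> 203 target

sig <- detect_signals(cases, "PT", map = synthetic_pt_soc_map())
print(sig, n = 5)
#> <faers_signals> level PT, 40 events, 2 positive (ranked by a)
#>   universe: 20000 reports, 203 target-drug
#>      event  a   ror ror_lo95   prr     chi2      ic  ic025  ebgm ebgm05 positive
#>  Dizziness 33 1.290    0.888 1.240   1.8100  0.3130 -0.241 1.240  0.853    FALSE
#>   Headache 33 0.985    0.677 0.988   0.0059 -0.0175 -0.560 0.988  0.679    FALSE
#>     Nausea 32 0.756    0.518 0.795   2.0900 -0.3280 -0.868 0.797  0.545    FALSE
#>      Sopor 26 7.930    5.190 7.040 128.0000  2.7300  1.840 6.640  4.340     TRUE
#>    Fatigue 22 0.773    0.495 0.797   1.3000 -0.3240 -0.954 0.799  0.512    FALSE
#>   ... 35 more events
```

Reading the `Sopor` row: 26 of the 203 target-drug reports carry the
event; it is reported ~7.9 times more often (odds) with the target drug
than with the background, all four lower bounds clear their thresholds
(`ror_lo95 = 5.19 > 1`, `PRR = 7.04 ≥ 2` with `χ² = 128 ≥ 4`,
`IC025 = 1.84 > 0`, `EBGM05 = 4.34 > 2`), so the pair is a positive
signal — the generator planted it at rate ratio 10. The common
background events (`Dizziness`, `Headache`, ...) sit near independence
and flag nothing. `detect_signals(..., rank_by = "ror")` re-ranks by
signal strength; `stratify()`, `volcano_data()` and `tto_distribution()`
produce the subgroup tables, and `run_pipeline(run_config(...))` writes
the whole artifact bundle (summary, signal, strata, volcano, TTO tables
and a run log) to a directory. A thin command-line front end lives at
`inst/cli/faerspv` (`faerspv synth`, `faerspv run`).

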