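---
title: "Disproportionality signal detection for spontaneous reports: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvkit)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect voluntarily submitted suspected adverse drug reaction
reports. They have no denominator: we never observe how many patients took a
drug, only how many reports mention it. Disproportionality analysis works
around this by asking whether an event is reported *relatively* more often
with the drug of interest than with all other drugs in the same database.
`pvkit` implements that analysis end to end for a single target drug — here
an anticonvulsant whose safety profile is dominated by nervous-system,
psychiatric, metabolic and serious cutaneous events — together with the data
cleaning FAERS requires, subgroup contrasts, and a time-to-onset model.

Because raw FAERS extracts are large and access is not reproducible inside a
test suite, the package ships a synthetic spontaneous-report generator that
emulates the quarterly ASCII layout with known ground truth. Everything the
pipeline claims is therefore checkable: planted associations must be
recovered, null data must stay quiet, and cleaning rules must do exactly
what they say on constructed corner cases.

## Cleaning model

A FAERS *case* (CASEID) may appear as several report *versions*
(PRIMARYIDs). Deduplication keeps, per case, the version with the latest FDA
receipt date, breaking ties by the highest PRIMARYID, and then removes cases
on the quarterly deleted-case list. The operation is idempotent and
order-independent, which the suite checks by permutation.

Target exposure is primary-suspect only: a report counts as exposed when at
least one of its drug rows matches the synonym dictionary (generic, trade
and development names; matching is case-, whitespace- and
punctuation-insensitive) *and* carries role code PS. Suspect-secondary,
concomitant and interacting mentions do not qualify.

The counting unit for the drug-versus-other contingency tables is the
*event record*: one distinct (report, PT) pair. A report listing the same
preferred term twice contributes one record; a report with five distinct
terms contributes five. Consequently `a + b` for the target drug equals its
total event-record count and is constant across PTs. Both the report-level
and record-level totals are exposed in the run manifest, since spontaneous-
reporting papers are often ambiguous about which one their background N is.

Ages arrive in mixed units and are converted to years (DEC ×10, YR ×1,
MON ÷12, WK ÷52.18, DY ÷365.25, HR ÷8766); converted ages above 120 years
are treated as missing. Sex codes other than F/M map to UNKNOWN. Dates are
CCYYMMDD strings; 4- or 6-digit partial dates are retained for display but
never enter time-to-onset.

## The four algorithms

For each PT the 2×2 table (a, b, c, d) with `N = a+b+c+d` feeds four
estimators:

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; positive when `a ≥ 3` and the
  lower bound exceeds 1.
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, interval
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`; same standard.
* **BCPNN information component**: observed
  `IC = log2[aN/((a+b)(a+c))]` with closed-form posterior moments under
  Beta/Dirichlet priors (defaults α = β = 2, α_i = β_j = γ_ij = 1); the
  signal bound is `E(IC) − 2·√V(IC) > 0` with `a ≥ 3`. We use the standard
  closed-form variance with the third term's denominator `(a+c+β_j)`;
  printed variants of this formula circulate with a transcription slip in
  that term, and the package's version is the one that satisfies the
  independence and prior-regularisation properties the tests enforce.
* **EBGM**: the default `corrected` dialect is the relative reporting ratio
  `aN/((a+b)(a+c))` with `EBGM05 = exp(ln EBGM − 1.96·√(1/a+1/b+1/c+1/d))`;
  positive when `a > 0` and `EBGM05 > 2`. An `as_printed` dialect
  `aN/((a+c)(b+d))` is available for comparison with sources that print it,
  but it violates the independence ⇒ 1 property and is not used by default.
  A full gamma-mixture empirical-Bayes prior fit (openEBGM-style) is out of
  scope.

A PT is a **combined positive** only when all four standards fire at once —
the conservative intersection rule. Exact independence
(`a/(a+b) = c/(c+d)`) gives ROR = PRR = EBGM = 1 and IC = 0 exactly, and
all point estimates are invariant to scaling the four cells; both facts are
enforced as invariant tests against an independently coded transcription of
the formulas on every small table.

Per-PT p-values are two-sided Fisher exact tests (exact for the sparse
cells typical here, and verified against exhaustive hypergeometric
enumeration), Bonferroni-corrected with `m` = the number of distinct PTs
observed for the target drug. Zero cells flag an estimate as undefined
rather than applying a continuity correction; a Haldane-style +0.5 would
silently shift every threshold, so it is deliberately not a default.

Aggregation reuses the same machinery at the SOC level (one count per
distinct report-SOC pair; unmapped PTs are reported as `UNMAPPED`, never
dropped) and at the narrow-SMQ level restricted to the combined-positive
set. MedDRA itself is licensed, so the package defines an open three-file
CSV mapping format and ships a clearly marked synthetic mini-dictionary
covering the terms the generator uses; real mappings drop in as files.
Designated-medical-event screening intersects the combined positives with a
user-supplied DME list and carries along same-SOC companion positives;
whether an event is listed in the drug label is user-supplied metadata, not
computed.

## Subgroup contrasts

The sex contrast builds a male-versus-female 2×2 *within* target-drug
reports of known sex, at the report level (a report either mentions the PT
or it does not), so its ROR estimates the report-level odds ratio the
generator plants. It uses the same Woolf interval; a PT is sex-differential
when the interval excludes 1.

Age groups are children < 18, adults 18 to < 65, elderly ≥ 65 (the 65.0
boundary goes to elderly), unknown kept apart. For each PT a logistic model
on the reports with known age and sex regresses PT presence on the
age-group factor (crude) and on age group plus sex (adjusted), adult group
as reference, Wald 95% intervals, IRLS convergence at log-likelihood change
< 1e−8 within 100 iterations. A contrast is reported as inestimable when
its arm or the reference arm has zero events or zero non-events — matching
the practice of leaving such odds ratios out of forest plots rather than
reporting boundary estimates. The crude OR on a saturated age-group model
equals the corresponding 2×2 cross-product ratio, which doubles as the
oracle test for the fitting path. Separation beyond the zero-arm check is
reported as non-convergence; a Firth correction would be the next step and
is intentionally not a silent default.

## Time to onset

TTO = event onset date − earliest complete therapy start date of the
primary-suspect target drug, in days. Non-positive differences and partial,
missing or invalid dates are excluded with per-reason counts in the
manifest. Summaries use linear-interpolation (type 7) quartiles and the
bins 1–30, 31–90, 91–180, 181–360, > 360 days.

The two-parameter Weibull density
`f(t) = (β/α)(t/α)^{β−1} exp(−(t/α)^β)` is fitted by maximum likelihood on
the log-parameters (BFGS, relative tolerance 1e−12, moment-based start from
the Gumbel representation of log t). Wald 95% intervals use the observed
information on the log scale and are back-transformed, so they are always
positive and always contain the point estimate. Censoring is out of scope.
Classification: shape CI entirely below 1 ⇒ *early failure* (hazard
decreasing — the typical adverse-event pattern where most onsets cluster in
the first weeks); entirely above 1 ⇒ *wear-out*; otherwise *random*. The CI
construction behind published shape intervals is rarely stated; the Wald
log-scale choice here is made for determinism, and the recovery tests
therefore check *coverage of the fit's own interval* at the published
sample size (n = 109, shape 0.69, scale 53.29 days) rather than chasing any
particular printed interval. A bootstrap alternative would be easy but is
not a default, again for determinism.

## The synthetic generator

The generator is first-class, tested code, not a fixture. Per case it
draws: one primary-suspect drug (target with probability 0.1, otherwise one
of eight comparator anticonvulsants — roughly the target-report share a
decade of quarterly files yields); sex (60/40 F/M before masking), a
three-band age group (11.4/71.4/17.2% children/adult/elderly), and PT
presence as independent Bernoulli draws over a ~29-term vocabulary mixing
common tolerability events with rare serious ones. Missingness follows the
pattern of consumer-dominated spontaneous data: 65.5% of ages, 87% of
weights and 29.5% of sexes are masked *after* the true values have driven
any planted effects, so estimators see realistic incompleteness while the
ground truth stays exact.

Associations are planted at the report level: for a planted (PT, odds
ratio) pair the target-arm probability is the odds-ratio shift of the
background probability, recorded to machine precision in the ground truth.
Planting acts on report generation, never on counts, so deduplication,
PS-selection and record counting are all exercised on the way to recovery.
Sex and age effects shift odds the same way within target reports (female
and adult arms stay at baseline). The default conditions plant odds ratios
10, 5 and 2 on three rare terms (background probability 0.003 — the
magnitude of rare serious events), a male/female seizure odds ratio of
1.64, and child/elderly psychiatric-event effects.

Two details matter for interpretation. First, the drug-versus-other 2×2 is
record-based while planting is report-level, so the record-level ROR sits
very slightly below the planted odds ratio when a planted term is common or
when several planted excesses share a dataset (they inflate each other's
`b` cell). With rare planted terms the gap is far inside the estimator's
own interval; the recovery tests additionally plant one association per
dataset so each is measured cleanly. Second, every report must carry at
least one PT, enforced by redrawing empty rows; this conditioning is common
to both arms and negligible at the default vocabulary mass.

Duplicates exercise both deduplication branches by construction: half the
duplicated cases get a later receipt date with a *lower* PRIMARYID (the
date rule must win), half an equal date with a higher PRIMARYID (the id
rule must win). A 2% slice of cases is flagged deleted; 5% of
therapy-start/onset dates are truncated to partial dates to exercise the
TTO exclusions; onset delays are Weibull(0.69, 53.29) days, rounded up to
at least one day.

What the generator does *not* emulate: correlated PTs within a report (real
reports cluster symptoms), drug-drug confounding, reporting-rate drift over
calendar time, country-specific reporting cultures, and free-text drug-name
noise beyond simple alias/case/spacing variation. Passing recovery tests
therefore demonstrates that the estimators and plumbing are correct, not
that the pipeline is robust to every bias a real spontaneous database
contains.

## Problem sizes and determinism

Calibration runs use 20,000 cases (about 2,000 target reports — the scale
of a single-drug FAERS extract) with 50 seeds per planted condition in the
test suite, 100 replicates of n = 109 for Weibull recovery, and exhaustive
enumeration over all 2,401 small tables for the estimator oracle; these
sizes give stable pass/fail behaviour while keeping a full run in minutes.
Every stochastic step flows from a single configuration seed;
identical configurations produce byte-identical tables and byte-identical
output bundles, which the suite checks with file hashes.

## Known limitations

* Disproportionality measures reporting association, not incidence or
  causation; the package deliberately stops at signal tables.
* The MGPS implementation is the closed-form shrinkage-free geometric mean
  with its conventional log-normal lower bound, not a fitted gamma-mixture
  prior.
* No Haldane correction, no Firth regression, no censored Weibull — each is
  noted where the choice bites, and each would change thresholds if bolted
  on silently.
* The bundled dictionary is synthetic and minimal; real MedDRA/SMQ/DME
  content must be supplied by the user as the documented CSV/text files.
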