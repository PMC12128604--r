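---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The data model and its assumptions

`faersignal` analyzes spontaneous adverse-event reports in the FAERS
quarterly ASCII data model: five dollar-delimited tables (DEMO, DRUG, REAC,
THER, OUTC) keyed by PRIMARYID, where a *case* (CASEID) may appear as
several report *versions* (PRIMARYIDs) as follow-up information arrives.
Spontaneous reports carry no denominator — nobody knows how many patients
took the drug — so nothing here is an incidence estimate. All statistics
are *reporting* statistics: they compare how often an event accompanies the
target drug against how often it accompanies everything else in the same
database, under the assumption that reporting biases act similarly on both
arms. That assumption is the standard one in pharmacovigilance screening
and is also its standard caveat.

Dates in FAERS are frequently partial (`YYYY`, `YYYYMM`, `YYYYMMDD`). The
package parses them into explicit partial dates rather than coercing them:
deduplication can use any precision (a month-precision receipt date sorts
before any day inside a later month), while time-to-onset arithmetic uses
day-precision dates only, because a month-precision interval would be
biased by up to ±30 days, which is material against a median near 100 days.

## Deduplication

Versions are grouped by CASEID; the version with the latest FDA_DT wins,
ties go to the numerically higher PRIMARYID (the later submission). A
version whose FDA_DT does not parse loses every comparison and survives
only if it is the sole version. The rule is idempotent and leaves exactly
one row per CASEID — both properties are asserted in the tests on generated
data with a 20% duplicate-injection rate.

## The reporting odds ratio

For one event term, deduplicated cases are cross-classified into the 2×2
table (a, b, c, d) by target-drug membership (primary-suspect role only)
and term occurrence. The counting unit is the case: a case reporting both
"Nausea" and "Vomiting" contributes once to each PT but only once to their
shared SOC, which prevents double counting at SOC level. The estimator is

ROR = (a·d)/(b·c),  95% CI = exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d))

with z fixed at 1.959964. The positivity rule — lower CI bound strictly
above 1 with a ≥ 3 — is the common FAERS screening criterion; it controls
neither family-wise error nor FDR, and no multiplicity adjustment is
applied, because the method's output is a screening shortlist, not a set of
confirmed associations.

Numerical choices:

* **Zero cells.** With a = 0 no estimate is reported (the term appears
  with its count and no CI). When a ≥ 3 and exactly one of b, c, d is
  zero, the Haldane–Anscombe correction (0.5 added to all four cells) is
  applied and the row is flagged `corrected`, preserving estimability for
  strong rare signals instead of discarding them.
* **Ranking.** Signal tables are ranked by frequency (n) or by ROR; ties
  break on the other key, then on term text, so output order is total and
  reproducible.

The estimator is checked two independent ways in the tests: against a
separately scripted closed-form oracle (same algebra, independent
arrangement, 1e-12 relative agreement over 1,000 random tables) and against
a saturated weighted logistic regression, whose drug coefficient equals the
log ROR and whose standard error equals √(1/a+1/b+1/c+1/d).

## Subgroups

The sex axis uses strata F and M (unknown sex excluded); the age axis uses
adults 18–64 and elderly ≥65 (under-18 and missing age excluded). Both the
cohort and the background are restricted to the stratum before tables are
built — a within-stratum background is the interpretation that keeps the
comparison "this event in elderly users of the drug vs other drugs in the
elderly" rather than contaminating the contrast with the age composition of
the whole database. Strata are compared by set algebra on their flagged
terms with RORs side by side; no interaction statistic is computed, since a
screening contrast between Wald intervals would invite over-interpretation.

## Time to onset

TTO = event onset date − earliest day-precision therapy start of the target
drug, in whole days. Same-day onsets are recoded to 0.5 day rather than
dropped: they are real first-day events and must enter the first bin and
the Weibull support (which excludes 0). Negative intervals and partial
dates become missing, with per-reason counts in the log. Bins are
right-closed at 30/60/90/180/360 days ("the first month" is (0,30]);
quantiles use linear interpolation (R type 7) — stated because IQRs differ
across quantile definitions. Cross-group comparisons use the
Kruskal–Wallis test with tie correction; the degenerate all-identical case
is defined as H = 0, p = 1.

The hazard shape per group is classified by a two-parameter Weibull fit,
uncensored maximum likelihood (only observed onsets are analyzed). The MLE
is computed by solving the one-dimensional profile equation in the shape
with a safeguarded Newton iteration in C++ — the profile function is
strictly decreasing, so the root is unique for any non-degenerate sample;
constant samples are rejected as a degeneracy error. The shape CI is a
nonparametric bootstrap percentile interval (default 1,000 resamples,
seeded); bootstrap rather than the asymptotic Wald interval because onset
samples are small-to-moderate and heavily skewed, where the Wald interval
for a positive parameter misbehaves. Classification: *early* (CI < 1),
*random* (CI ∋ 1), *wear-out* (CI > 1). Fits require n ≥ 10; smaller
groups report median/IQR only.

## The synthetic generator: what it emulates, what it does not

The generator exists so that every stage has a ground truth. Its defaults
describe a desk-scale spontaneous-report universe:

* 100 synthetic PTs in 15 synthetic SOCs with baseline probabilities
  log-spaced over 0.002–0.15 (≈3.5 PTs per case, a long rare-term tail,
  ≈3% zero-reaction reports which the case builder drops and counts).
* `target_drug_prob = 0.05`: a cohort of ~1,000 at n = 20,000, the order
  of a single-drug FAERS cohort, while keeping simulations fast.
* Signals are planted on the **odds-ratio scale**: the target-arm
  probability is raised so the case-level odds ratio equals the planted ρ
  exactly, making the disproportionality module's estimand coincide with
  the ground truth (a rate-ratio planting would not).
* Onset models are per-SOC Weibulls (two constant-hazard classes, the
  rest decreasing-hazard, scales 60–190 days, pooled median near 100
  days). One uniformly chosen reaction per case — the *index* reaction —
  drives the report's single event date, and the manifest records it, so
  onset ground truth is checked on index reactions.
* Demographic mix: 84% female, ~60% missing age, 83% consumer-reported,
  ~99.5% US — the case mix typical of a recently approved specialty drug.
* 20% duplicate injection (an earlier version with a lower PRIMARYID; a
  quarter of duplicates share the FDA_DT to exercise the tie-break), and
  10% date degradation (half to month precision, half missing).

Deliberately **not** emulated: co-occurrence structure between PTs (drawn
independently; no analysis here depends on it), drug co-prescription
networks, free-text drug-name noise beyond trade/strength variants,
reporting-delay truncation, and secular reporting trends. Consequently,
passing tests demonstrate the *estimators and plumbing* are correct under
known truth — they cannot certify behavior under real-world reporting
biases, which no synthetic benchmark can.

## Problem sizes and simulation budgets

Validation uses n = 50,000 cases for the null false-positive check (all
planted odds ratios 1; expected per-term flag rate is the one-sided 2.5%
plus small-count Wald slack, bounded at 7% of the catalog), 100 generator
seeds at n = 20,000 for recovery of a planted odds ratio of 5, n = 2,000
with 1,000 bootstrap resamples for Weibull shape recovery (±0.05) and 100
replicates for classification rates, and 1,000 null replicates for the
Kruskal–Wallis type-I error (accepted inside 3.7–6.3% at α = 0.05). These
sizes give Monte-Carlo error comfortably below each acceptance band while
keeping a full validation run in the low minutes on one core.

## Known limitations

* Reporting odds ratios are screening statistics; confounding by
  indication, stimulated reporting and channeling are not addressed.
* The PT→SOC dictionary is user-supplied; results are MedDRA-version
  sensitive in principle.
* Onset analysis ignores censoring and truncation: a drug recently on the
  market cannot yet have reported long-latency events, biasing Weibull
  shapes toward early failure. The fit describes the observed reporting
  pattern, not the latent hazard.
* A report's single event date is applied to all of its reactions; FAERS
  does not provide per-reaction onset dates.
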