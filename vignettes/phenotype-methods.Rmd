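---
title: "Methods: the two-step B-NHL claims phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step B-NHL claims phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnhlphenotype)
```

## The problem and the model

Administrative claims record what a hospital billed, not what a patient
had. For pediatric mature B-cell non-Hodgkin lymphoma (B-NHL), a
diagnosis-code query is sensitive but unspecific: T-cell and Hodgkin
lymphomas, relapsed disease, transfers-in for second opinions, and plain
miscoding all carry the same codes. The phenotype implemented here
treats chemotherapy billing as the disambiguating signal: de novo B-NHL
in North American children's hospitals is treated on a small set of
well-defined multi-agent cycles, so a patient whose dated drug bills
reproduce one of those cycle sequences almost certainly has the disease.

The procedure is a deterministic classifier, not a fitted model. Its
assumptions are worth stating plainly:

* **Complete pharmacy billing.** A drug administered but not billed
  looks like an absent drug class. The one-missing-class tolerance
  absorbs isolated billing gaps; systematic gaps produce false
  negatives.
* **Day-resolution timestamps.** All logic is integer day arithmetic;
  calendar parsing happens only at the file boundary, and day windows
  are half-open (`[start, start + n)`), so "the following 45 days" means
  45 whole days beginning the day after the reference day.
* **Institution-scoped identifiers.** A patient is a
  `(institution_id, patient_id)` pair; care delivered elsewhere is
  invisible, which is exactly the transfer-in failure mode the
  validation quantifies.

## Step 1: code screen and billing filter

An admission qualifies if any of its diagnosis codes, in any position,
matches a screening-table entry of the same code system by *prefix*
(entry `200.2` matches any billed code beginning `200.2`). The index
admission is the earliest qualifying one, ties broken by discharge date
and then input order, giving a deterministic anchor for the review
window. Screened patients are excluded only if they lack billing for
*all* screen agents; a single bill for one agent keeps them in. The
shipped screen list has the twelve agents named across the standard
regimens; regimen descriptions in the source protocols reference a
thirteenth pre-specified agent that is never named, so the list is
config-extensible (`ontology.yaml`).

## Step 2: cycle segmentation and fuzzy template matching

**Segmentation.** Candidate cycles are maximal runs of *chemotherapy
days* (days with at least one non-steroid bill) in which consecutive
chemotherapy days are separated by fewer than `segmentation_gap_days`
(default 7). Steroid-only days never open or bridge a group — oral
steroid tails would otherwise fuse adjacent cycles. The 7-day default is
a design choice rather than a published rule: intra-cycle spans are at
most about 5 days and inter-cycle gaps at least about 21, so any
threshold in (5, 21) segments identically; 7 is conservative.

**Matching.** Each template is a set of required drug classes with
canonical day offsets in a 5-day window (day 0 = first administered
agent). The published schedules pin down each cycle's *composition*; the
canonical offsets are package defaults chosen so the tolerance rules,
not the offsets, carry the semantics, and they are fully
config-overridable with trial-accurate schedules. A candidate matches a
template if some anchor day aligns every non-optional class to within
`max_shift_days` (default 2) of its offset, allowing at most
`max_missing_classes` (default 1) absent classes. Three refinements:

* **Steroids never penalise.** Bills in the steroid classes (the
  prednisone family, and dexamethasone as a separate class used only
  where a template names it) are ignored for voiding and may be
  arbitrarily numerous; only the steroid class's *presence* near its
  offset is scored.
* **Foreign cytotoxics void.** Any non-steroid agent outside the
  template's classes voids the match. Without this, ABVD-like or
  T-cell-protocol billing — the dominant false-positive class — would
  match B-NHL templates by subset.
* **Distinguishing classes.** A class marked `distinguishing` may never
  be the absent one. Only COPAD's doxorubicin is marked by default: COP
  is a strict subset of COPAD minus doxorubicin, and two COP cycles must
  not qualify as two COPADs. Other templates keep the full
  one-missing-class tolerance.

Among feasible anchors the matcher reports the one minimising (number of
missing classes, maximum day shift), ties broken by the earliest anchor;
this is exhaustive-search-equivalent, and the test suite verifies that
against an independent brute-force enumerator over anchors and
missing-class assignments. One consequence worth knowing: a deviation of
+3 days on a single class can still match with zero missing classes,
because a whole-cycle anchor shift of 1–2 days may absorb it while every
other class stays within tolerance. Empty candidates, all-steroid bill
sets, and patients with no bills in the window all degrade to "no
match", never to errors.

## Inclusion rules

Rules are evaluated in priority order over matches in
`[index, index + 45)`; the order affects only the reported label, since
inclusion is their disjunction:

1. `TWO_CYCLE_STANDARD` — a COPADM/R-COPADM plus a preceding COP or a
   second COPADM/R-COPADM. A lone COPADM is insufficient: the two-course
   requirement is preserved.
2. `TWO_COPAD` — two COPAD courses.
3. `REPOCH_PAIR` — at least two R-EPOCH cycles (a preceding COP is
   permitted but not required).
4. `BFM95_SEQUENCE` — BFM-95 course 1 followed by course 2.
5. `COP_ONLY_NO_RETURN` — at least one COP cycle and no inpatient
   encounter in the 45 days after that admission's discharge. This
   captures patients who do not survive to a second course. "At least
   one" matters: requiring *exactly* one would let a loosened tolerance
   create a second COP match and flip an included patient to excluded,
   breaking monotonicity.
6. `LOOKBACK_RESCUE` — when rules 1–5 fail but the window contains at
   least one matched cycle, the review extends to
   `[index − 60, index + 45)` and rules 1–4 are re-applied. The trigger
   is deliberately broad ("any unpaired matched cycle") because the
   specific later-course patterns that should prompt a lookback are not
   enumerable a priori: a lone COPADM in-window with a COPADM 40 days
   before the index admission is exactly the mid-protocol-first-coded
   patient the lookback exists for, and a lone BFM-95 course 2 with an
   empty lookback stays excluded either way.

Because every rule is monotone in the match set, loosening
`max_shift_days` or `max_missing_classes` can only add matches and never
turns an included patient into an excluded one — a property the test
suite sweeps explicitly.

## Validation statistics

Sensitivity and PPV intervals are Clopper–Pearson exact binomial by
default; this is the method that reproduces the published validation
intervals digit for digit, and a Wilson score option exists for users
who prefer shorter intervals. Chi-square comparisons use Pearson's
statistic without continuity correction; the race comparison drops the
Other/Unknown categories (absent from the registry reference), and the
shipped reference table already excludes the handful of patients aged
20–21 that the registry's age bands do not cover. Cohen's kappa is
computed from the 2×2 verdict marginals; when both raters use a single
category (chance agreement 1), kappa is defined as 1 for perfect
agreement and 0 otherwise.

## The synthetic generator

`simulate_claims()` draws a labelled cohort whose structure mirrors what
code-based screening encounters in practice. Each patient receives one
gold label with default mixture: 60% true de novo B-NHL (the share of
true cases among screen-positive patients in single-centre validation,
103/173), the rest split 85.7% / 1.4% / 10.0% / 2.9% across alternate
diagnoses, relapsed disease, transfers-in, and coding without
malignancy. True patients are treated on a qualifying plan (weights
favouring COPADM/R-COPADM sequences, which dominate in practice) with
deviations drawn *within* tolerance: per-class day shifts uniform on
{0, 1, 2}, one class dropped with probability 0.1 per cycle (never a
distinguishing class), extra steroid days Poisson(2), inter-cycle gap 21
days. A fraction 9/106 of true patients are planted false negatives,
split 5:4 between a missing screening code and regimens altered beyond
tolerance (two classes removed per cycle, so no template can match).
Alternate-diagnosis patients get screening codes plus ABVD-like billing
whose foreign agents void every template; 4/60 of them — and all
relapsed patients — are treated on genuine B-NHL regimens and therefore
survive review as false positives, matching the residual
false-positive composition after manual review. Transfers-in receive a
single late-course cycle; demographics are sampled independently of
label from the assembled-cohort category frequencies.

Patients constructed as detectable must satisfy an inclusion rule
*exactly*; the generator verifies this by running the matcher as a
self-test during generation (disable with `self_test = FALSE` for large
label-only draws). Generation is a pure function of the spec and seed.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: billing-dialect noise beyond a small
synonym map, supportive-care drugs interleaved with chemotherapy,
institution-specific coding practices, dose and route information,
length-of-stay structure, and transfers-in who continue multi-cycle
therapy (such patients would be included by any two-course rule, since
billing alone cannot reveal that therapy started elsewhere; the
validation literature attributes their exclusion to human review). The
relapsed patient's claims signature — a prior-era treatment block 150
days before the index admission, then full re-treatment — is a
plausible stand-in, not an observed pattern.

## Problem sizes and numerical conventions

The test suite and acceptance script use cohorts of 200–1,000 patients
for end-to-end checks, 500 random candidate cycles (≤ 12 bills) for
matcher/oracle equivalence, a 6-point tolerance sweep for monotonicity,
and a 10,000-patient generation for false-positive-mixture calibration
against exact binomial 99% bounds; these sizes give stable proportions
while keeping a full run in the low minutes on one core. All randomness
flows from a single integer seed. Dates are integers (days since
1970-01-01) internally and ISO-8601 at every file boundary.

## Known limitations

The phenotype inherits the failure modes its validation quantifies:
patients treated on altered regimens are invisible (false negatives),
and relapsed or miscoded patients treated on full B-NHL regimens are
indistinguishable from de novo disease (false positives). Emergency-
department-only encounters are treated as admissions, and the study-era
restriction of codes (ICD-9 before, ICD-10 after a cutover) is left to
the caller — any admission may carry either system. The headline counts
of a multi-institution cohort cannot be reproduced without proprietary
source data; the package substitutes property-based guarantees on
synthetic cohorts for them.
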