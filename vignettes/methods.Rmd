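---
title: "Methods: within-trial cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-trial cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## The evaluation problem

`trialcea` implements a within-trial economic evaluation of facilitated
access to a web-based self-management programme for adults with type 2
diabetes, against usual care plus an information-only website, from the
perspective of the health service and personal social services. The trial
structure it targets: 374 adults individually randomized 1:1 in permuted
blocks of 2, 4 and 6 stratified across 21 primary-care centres, followed
for 12 months, with assessments at baseline, 3 and 12 months. All costs are
in pounds sterling at 2014 prices; neither costs nor outcomes are
discounted, the horizon being a single year.

Two health outcomes are carried in parallel: quality-adjusted life years
(QALYs) from EQ-5D-3L, and diabetes-related distress from the 20-item PAID
scale (0–100, lower is better, ≥40 flags significant distress).

## Costing model

### Intervention micro-costing

The intervention cost separates into a **fixed annual operating cost** —
staff activities (content updating, forum moderation, engagement
newsletters, clinical input, patient-representative payments) plus
infrastructure (hosting, maintenance, domains, certificates) — and
**per-user components**: one-off nurse training and a facilitated
registration session (20 minutes of practice-nurse time at £44/h plus a
£0.95 booklet). Development costs are excluded: they were research-funded
and would not recur in routine rollout. The control arm carries zero
intervention cost, the comparator website's costs being a research
artefact.

Staff activities are costed as hours per occasion × occasions per year ×
hourly rate, rounded to whole pounds. The packaged schedule also carries
the reported annual figure per row; three rows cannot be reproduced from
any single annualization convention (they imply, e.g., a 7.55-hour working
day), all disagreeing by under 2%. The reported figures are therefore
authoritative for totals (`mode = "printed"`, the default), the formula
mode is available for audit, and `staff_activity_costs()` exposes the
per-row relative disagreement. With the packaged inputs the operating cost
is £18,783 (staff) + £23,013 (infrastructure) = £41,796/year; spread over
the 185 intervention-arm participants and adding training (£3,863/185) and
facilitation, the per-participant cost is £226 + £21 + £16 = £263 in
rounded-component mode. Rounding each component to the nearest pound before
summation is the default because that is how per-participant figures are
conventionally reported; exact summation (`rounding = "unrounded"`) gives
≈£262.4 and is available throughout.

### Health-service costing

Resource-use counts are multiplied by national average unit costs (VAT,
on-costs and overheads already embedded — never applied twice) and summed
within three aggregated sections per collection window: nurse-recorded
services, nurse-recorded prescriptions, and self-reported services. The
windows are the 12 months before baseline, months 0–3, and months 3–12.
Two rules matter downstream:

* **Missing-section rule**: any missing individual service makes the whole
  section cost missing (a partial sum would understate use). The rule is
  idempotent and order-independent.
* **Chronic-prescription assumption**: current prescriptions are assumed
  issued monthly over the whole window (×12, ×3, ×9). A blank prescription
  record is missing unless "no medication" was stated explicitly, which is
  a zero.

## Outcome scoring

EQ-5D-3L profiles map to utilities through the UK time-trade-off tariff in
additive-decrement form: full health anchors at 1; any departure subtracts
a constant 0.081, per-dimension level decrements, and 0.269 more if any
dimension is at level 3; the worst state (33333) scores −0.594. The value
set ships as a CSV with a provenance header and a checksum; the scorer
refuses to run against a file whose checksum does not match, so a corrupted
transcription can never silently score utilities. The test suite compares
the scorer against a second, independently written transcription on all 243
states.

QALYs are the trapezoidal area under the utility curve,
`0.125·u0 + 0.5·u3 + 0.375·u12`. Because this is linear, the mean of
per-participant QALYs equals the AUC of mean utilities exactly — a property
the tests assert, and the reason published arm-mean utilities reproduce the
published arm QALYs (0.802 in the intervention arm) to rounding.

Twelve-month questionnaires answered outside a 10–14-month window are
invalid as outcomes but are kept as auxiliary predictors for imputation.
Both window boundaries are treated as inclusive; the source convention is
unstated, and a closed interval is the least surprising reading of
"window of 10–14 months".

## Missing data

Missing aggregated variables — the nine section costs, PAID totals and
utilities at each timepoint, and diabetes duration — are multiply imputed
by chained equations with predictive mean matching, **separately by
randomized group**, with m = 30 by default (matching the rule of thumb
that m should be at least the percentage of missing information, bounded
here by 30%).

Choices the source leaves open, fixed as follows:

* Variables are visited in ascending order of missingness; 10 cycles per
  imputation; initial fills are random draws from the observed values.
* Prediction models are linear regressions of each variable on all other
  aggregated variables, the complete baseline covariates (age, sex,
  cardiovascular history, smoking; binary as indicators), and the
  out-of-window 12-month measurements as auxiliary predictors (mean-filled,
  never imputed).
* Matching is "type 1": observed cases are predicted with the maximum
  likelihood coefficients, missing cases with coefficients drawn from their
  posterior (σ² from a scaled inverse-χ², β | σ² normal). The donor pool is
  the k = 5 observed cases nearest in predicted mean; ties are broken by a
  seeded uniform jitter. The parameter draw is what propagates estimation
  uncertainty into the between-imputation variance; matching on fixed
  coefficients is known to understate it.

Imputed values are always observed values of the same arm (no out-of-support
imputations), observed cells are immutable across copies, and everything is
deterministic given the seed. The complete-case filter (`cca_filter()`)
implements the comparison analysis, retaining rows complete on the
covariates, all section costs and both outcomes at every timepoint.

## Incremental estimation and uncertainty

Each completed copy is analysed per endpoint (total 12-month cost including
the intervention cost, QALY, 12-month PAID) with a linear mixed model: fixed
effects for arm, age, sex, cardiovascular history, smoking, diabetes
duration and the corresponding baseline endpoint; a random intercept per
centre; no interactions or time terms. REML fits that are singular (zero
estimated centre variance) fall back to ordinary least squares with a
warning — in that degenerate case the estimators coincide, which the tests
check at 1e-6. Estimates are pooled by Rubin's rules (total variance =
within + (1 + 1/m) × between; t reference with the standard MI degrees of
freedom).

ICERs divide pooled Δcost by pooled Δeffect, and are always reported with
their plane quadrant because a bare negative ratio is ambiguous. The PAID
ICER is cost per unit *improvement* (sign-flipped).

The bootstrap resamples participants with replacement, stratified by arm,
from the original incomplete data; each replicate is singly imputed with a
fresh stochastic PMM pass and refitted, keeping each replicate's cost and
effect paired. How the source combined bootstrap and imputation is not
stated; resample-then-impute with the m = 30 analysis reserved for point
estimates is standard practice and tractable at thousands of replicates.
Replicate fits use ordinary least squares by default (`use_lmm = TRUE` is
available): with 21 centres the centre variance contributes little to the
arm contrast, and the difference is well under bootstrap noise. Percentile
intervals (not BCa) summarise the cloud. The CEAC reports
P(λ·ΔE − ΔC > 0) on a £0–50,000 grid (£500 steps, the £20k and £30k
thresholds always included); it is defined for QALYs only — there is no
accepted willingness-to-pay per PAID unit, so a PAID CEAC is refused rather
than fabricated. Replicates with Δeffect exactly 0 count as not
cost-effective (measure-zero under continuous data).

`ceac_normal()` gives the closed-form CEAC for a bivariate-normal
incremental distribution; with the reference moments (means 111 and 0.020,
SDs recovered from the reported CI half-widths) and any cost–effect
correlation in [0, 0.3], the probability at £20,000/QALY lies in
0.86–0.90, consistent with the reported 87% — the correlation itself was
never reported, so the reproduction is necessarily approximate.

## Scale sensitivity and break-even

Operating costs are fixed up to the server capacity of 10,000 users, so the
per-user cost falls as 41,796/n while training and facilitation stay
per-user (training conservatively held constant per user despite likely
economies). Holding the trial's healthcare cost difference and QALY gain
fixed,

```
ICER(n) = (41796/n + 37 + Δhealthcare) / ΔQALY,  Δhealthcare = 111 − 263 = −152
```

The fixed share is kept continuous in n so the curve is strictly monotone;
rounding (the default elsewhere) applies to the per-user variable
components. The break-even count solves the numerator for zero:
41,796/115 ≈ 363.4, i.e. 363 users in rounded-component mode (unrounded
components give ≈363.7 → 364; both are reported). Around 81 users the ratio
passes the £20,000/QALY threshold.

## The synthetic trial generator

No participant-level data were deposited, so the generator defines the
study conditions under which the pipeline is exercised and tested. Its
defaults are the published arm-level summaries: arm sizes 185/189 over 21
centres (realized sizes come from the blocked randomization itself), age
64.9/64.7 (SD 9.5/9.1), 69% male, diabetes duration 7.8/8.2 years, mean
utilities (0.793, 0.811, 0.793) and (0.766, 0.786, 0.736), PAID
(18.1, 15.7, 14.5) and (19.9, 17.3, 17.6), and mean section-cost totals
1792/2084 (baseline year) and 1816/2067 (trial year). Where the summaries
are silent a single realistic choice was fixed: 25% cardiovascular history
and 15% smokers; cost coefficient of variation 0.86 (complete-case SDs ≈
means, hence gamma section totals); section split 55% nurse-recorded
services / 30% prescriptions / 15% self-report; window split 25%/75% for
months 0–3/3–12; centre-level SDs of £150 / 0.02 utility / 2 PAID points.

Three design points deserve explanation:

* **Embedded effects, not just means.** Follow-up intervention-arm means
  are derived from the target adjusted incrementals (ΔC = £111,
  ΔQALY = 0.020, ΔPAID = −1.9) through shared baseline slopes
  (b = 0.339 cost, 0.587 utility, 0.667 PAID), chosen so that with the
  published baseline imbalances the *baseline-adjusted* arm effects equal
  the targets while the unadjusted differences reproduce the published £12,
  0.038 and −3.1. With the default targets the derived follow-up means are
  exactly the published ones.
* **Utilities live on the tariff grid.** Latent normal trajectories are
  snapped to the nearest of the 243 tariff values and realized as actual
  EQ-5D profiles, so the scorer is exercised end-to-end. The latent means
  are calibrated by root-finding so the *snapped* means hit the targets;
  PAID is calibrated the same way on its discrete 0–100 grid (1.25
  spacing), which removes the discretization bias a continuous
  censored-normal approximation leaves behind. Service counts are integer
  realizations (floor + Bernoulli remainder) of gamma section totals, and
  the trial-period total is built on the *realized costed baseline* so that
  count discretization cannot attenuate the baseline-adjustment slope.
* **Missingness is MAR by construction.** Questionnaires (EQ-5D, PAID,
  self-report services, assessment date) go missing as a unit at rates
  23%/20% (3 months) and 30%/29% (12 months), with non-response depending
  only on baseline distress (always observed) through a logistic model
  whose intercept is calibrated to the marginal rate, and with 12-month
  non-response more likely after 3-month non-response. Nurse-recorded
  sections drop independently at 2% per window; duration is missing for
  ~1%. The mechanism never involves the removed value. The 12-month
  assessment month is jittered as a truncated Normal(12.3, 0.8) months, so
  ~2% of visits fall outside the validity window and the filter has real
  work to do; a wider jitter would push outcome missingness past the 30%
  bound the design respects.

What the generator does **not** emulate: item-level questionnaire
missingness (questionnaire-level only), electronic-record extraction
artefacts, drug-name matching against a prescription cost database
(items arrive with a monthly cost attached), informative missingness
(MNAR), or non-trivial correlation between cost sections beyond the shared
participant total. Passing tests therefore demonstrate that the pipeline
recovers known truths under a faithful but idealized data mechanism — not
that any particular real dataset satisfies MAR.

## Problem sizes used in the test suite

The calibration invariant is checked at n ∈ {100, 1,000, 10,000}
participants; the parameter-recovery experiment runs 100 independent trials
at the full 374-participant scale with m = 5 imputations each, asking the
pooled 95% CIs to cover the embedded truth in at least 90; bootstrap and
pipeline tests use deliberately small replicate counts (tens to hundreds),
with B = 5,000 remaining the analysis default. m = 5 in the recovery loop
trades a slight widening of Rubin CIs for a hundredfold repetition; the
coverage criterion is calibrated to that choice.

## Known limitations

* The imputation model is single-level; centre effects enter the analysis
  model but not the imputation model.
* PMM donor pools of 5 can recycle donors heavily in small arms.
* The bootstrap treats the imputation model as fixed per replicate (one
  stochastic pass), which is standard but not the only defensible
  combination.
* Replication mode reproduces published arithmetic exactly; quantities that
  depend on unpublished participant-level data (the adjusted incrementals
  themselves, complete-case retention, exact CEAC values) are reproduced
  only distributionally, via the generator and closed-form oracles.
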