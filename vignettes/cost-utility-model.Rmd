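---
title: "A Markov cohort model for combined breast-cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for combined breast-cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcscreen)
```

## The decision problem

An urban Chinese screening programme offers women aged 35–65 a
combined pathway every two years: clinical breast examination (CBE)
with breast ultrasound (BUS) for everyone, supplementary mammography
(MAM) for BI-RADS 0/III triage, and biopsy for BI-RADS IV+ findings.
`bcscreen` evaluates the lifetime cost-utility of this programme and
of 26 alternatives that vary the starting age (35/40/45), stopping age
(65/69/74) and interval (1/2/3 years), against a no-screening
comparator.

## Model structure and assumptions

The engine (`run_cohort()`) is a deterministic cohort state-transition
model. A closed cohort enters 100% healthy at age 35 and is advanced
over 50 annual cycles (to age 84) through mutually exclusive states:
`Healthy`, diagnosed `DCIS`, diagnosed invasive stages `I`–`IV`, and
two absorbing death states (breast-cancer and other-cause). Within
each cycle, in order:

1. **Screening** (if the age is on the strategy's schedule, at the
   start of the cycle): the never-diagnosed pool attends. Costs follow
   the triage pathway (`screening_cycle_cost()`): everyone pays CBE +
   BUS; a fraction `f_mam` (22.9%) pays MAM; biopsies are paid by true
   positives (incident cases × sensitivity) and false positives
   (disease-free attendees × (1 − specificity)).
2. **Incidence**: healthy women develop breast cancer at the
   age-specific rate λ(age). In a screening cycle an incident case is
   screen-detected with probability equal to the test sensitivity
   (0.851) and draws her diagnosis stage from the screen-detected
   stage mix; otherwise she is clinically diagnosed *in the same
   cycle* with the clinically detected stage mix. The entire modelled
   benefit of screening is this stage shift at diagnosis.
3. **Progression and death**: diagnosed DCIS becomes diagnosed stage I
   with annual probability `rr_dcis × λ(age)` (the in-situ excess risk
   is expressed relative to background incidence); invasive stages
   progress (I→II 0.06, II→III 0.11, I→IV 0.01, II→IV 0.08, III→IV
   0.21 per year) and die of breast cancer at stage-specific rates
   (0.002/0.016/0.039/0.2331). All alive states face other-cause
   mortality `mu_other(age)`. Competing flows are applied as
   independent annual probabilities from the start-of-cycle mass; the
   engine refuses to run (with a named state and age) if any state's
   outgoing mass would exceed 1, rather than renormalising silently.
4. **Accrual**: utilities by start-of-cycle state (healthy 1, DCIS
   0.95, stages 0.9/0.8/0.7/0.3, death 0); one-off treatment +
   direct non-medical costs in the diagnosis cycle, with the treatment
   column chosen by detection mode; recurring outpatient costs every
   cycle spent diagnosed, including the diagnosis cycle.
5. **Discounting** by `(1 + r)^(−t)` with `t = 0` at age 35 and
   r = 3%/year for both costs and QALYs.

Population-level background breast-cancer mortality (printed alongside
all-cause mortality in the life-table inputs) is *not* applied on top
of the stage-specific mortality of diagnosed states: it is
calibration-level data, and double-counting it would bias survival
down in both arms.

### Structural switches

Two places where reasonable model structures genuinely differ are
exposed in `cohort_options()` rather than hard-coded:

- `half_cycle`: the default accrues utilities and recurring costs for
  the full cycle in the start-of-cycle state, the default behaviour of
  widely used decision-tree software; setting `half_cycle = TRUE`
  averages start- and end-of-cycle occupancy instead.
- `missed_carryover`: the default diagnoses screen-missed cases
  clinically in the same cycle. The alternative keeps them one cycle
  in an undiagnosed pool (healthy utility) before they present — a
  stylised one-year diagnostic delay. A full pre-clinical natural
  history (sojourn-time distribution, pre-clinical stage progression)
  is out of scope: the available inputs contain no parameters for it,
  and an undiagnosed pool *without* pre-clinical progression makes
  screening look harmful (undiagnosed cases would enjoy healthy
  utility with no excess mortality), which is why same-cycle diagnosis
  is the reference structure.

Because of exactly this under-determination — detection timing, cost
timing and cycle-correction conventions are internal choices of the
software a published analysis was built in, not recoverable from its
printed parameter tables — reproductions of published cost-utility
results from the same inputs can differ materially in the *levels* of
costs and ICURs even when the qualitative conclusions (frontier
composition and willingness-to-pay verdicts) agree. The package
therefore treats the printed parameter tables as the authoritative
inputs and documents its own structure completely, rather than tuning
hidden structure to match published outputs.

## Parameters

`default_parameters()` packages the base case: age-banded incidence
(10 bands, 35 to 80+) and mortality (11 bands, to 85+, with
`mu_other = mu_all − mu_bc` enforced to 1e-6), the two stage mixes at
diagnosis, unit costs (CBE 33, BUS 120, MAM 249.33, biopsy 184 CNY),
per-stage one-off treatment costs by detection mode, recurring annual
outpatient costs and one-off direct non-medical costs (each with a
printed low–high range), utilities, test performance (sensitivity
0.851 (0.758–0.944), specificity 0.967 (0.963–0.971)), and economic
settings (discount rate 3%, per-capita GDP 179,000 CNY, thresholds 1×
and 3× GDP, cohort 100,000, start age 35, 50 cycles).

Two triage fractions are needed by the costing model and are exposed
as parameters: `f_mam = 0.229` (share of screened women triaged to
supplementary MAM) and `f_referral_pos = 0.023` (share referred
BI-RADS IV+, used by the synthetic registry). They are programme-level
observations rather than test characteristics.

Everything is overridable through a YAML/JSON config
(`load_parameters()`), with age-banded tables acceptable inline or as
CSV files; `validate_parameters()` reports every violated invariant
(probabilities in [0,1], stage shares summing to 1, `low ≤ base ≤
high`, band coverage of ages 35–85, per-stage outgoing mass ≤ 1)
without raising, and `load_parameters()` refuses invalid configs.

## Strategy comparison

`run_strategy_set()` produces one discounted (cost, QALY) point per
strategy; `frontier()` sorts by effect, removes strictly dominated
points, then iteratively removes extended-dominated points until the
sequential ICURs strictly increase — the textbook convex-hull
construction, asserted on every run. Ties are deterministic: equal
effect keeps the cheaper strategy; exact duplicates keep the
lexicographically first label. `classify_icur()` maps an ICUR to
highly cost-effective (< 1× GDP), cost-effective (< 3× GDP) or not
cost-effective. Reports round ICURs to 2 decimals; comparisons always
use full precision.

## Sensitivity analysis

**One-way (tornado)**: `default_dsa_ranges()` uses the printed ranges
where they exist (stage costs, test performance) and conventional
ranges elsewhere — discount rate 0–5%, screening unit costs ±20%,
utilities ±10% capped at [0,1] (healthy utility stays 1 by
definition). These conventions are deliberate, documented choices:
the inputs print no ranges for those quantities. `tornado()` re-runs
both cohorts at each range end and sorts by swing.

**Probabilistic**: `assign_distributions()` builds beta distributions
for probabilities/utilities and gamma distributions for costs by
method of moments, reading each (low, high) range as a 95% interval
(`sd = (high − low)/3.92`) centred on the base value — the standard
construction when an analysis's own distribution tables are not
available. The discount rate is excluded from the probabilistic
analysis: it is a policy convention, not a measurable quantity with
sampling uncertainty, so it is varied one-way only. Parameters are
sampled independently; no correlation structure is asserted by the
inputs. `run_psa()` draws all parameters jointly per iteration
(defaults: 1,000 iterations, matching the study design and taking
seconds on one CPU), re-runs both cohorts, and summarises the draws by
net-benefit acceptability (`ΔE·WTP − ΔC ≥ 0`, which stays coherent
when ΔE is negative, unlike the raw ICUR sign) and a 95% confidence
ellipse (sample mean and covariance scaled by the χ²(2) 0.95 quantile,
5.991).

Reproducibility contract: one root seed; each parameter draw uses a
substream derived deterministically from (seed, parameter identifier,
iteration), so runs are bit-identical given the seed and adding or
removing a parameter never perturbs the other draws. Invalid draws
(a probability outside [0,1]) are redrawn and counted.

## Registry statistics and the synthetic registry

`summarize_registry()` aggregates either individual screening records
or pre-grouped stage counts: detection rates per 100,000 (overall to
2 decimals, per group to the nearest integer — the reporting
convention of the source table), case shares (2 decimals) and the
early-diagnosis rate (DCIS + stage I + stage II over all cases,
nearest integer). "Early" includes DCIS: the packaged table's printed
88% rate only reproduces from its own counts under that reading, so
the stage-0 column is treated as in-situ disease despite an ambiguous
abbreviation note in the source. The packaged table's totals row also
disagrees with the sum of its group rows (724 vs 713 cases; 699,600 vs
697,384 screened); the summary uses the explicit totals row for
overall statistics and surfaces the mismatch in its `consistency`
field instead of hiding or "fixing" it.

`generate_registry()` draws individual records with a configured age
mix (uniform within bands — only band totals are observable), per-band
detection probability, stage mix and triage rates. It emulates a
single cross-sectional screening round: no repeat attendance, no
interval cancers, no costs (economic quantities live exclusively in
the cohort model, keeping the two data paths independent). Passing
recovery tests therefore show the estimator arithmetic and the
generator agree at realistic sample sizes — not that real registry
data meets these idealised assumptions.

## Numerical choices and degenerate inputs

- Occupancy conservation is asserted every cycle at 1e-9; the engine
  is validated against a hand-enumerated oracle at 1e-12 on small
  models.
- Frontier ICUR monotonicity is asserted on every construction;
  equal-ICUR collinear points are pruned as extended-dominated, so the
  frontier is minimal.
- `icur()` refuses equal effects (undefined ratio) rather than
  returning ±Inf.
- Empty registries and zero-width sensitivity ranges are flagged
  (undefined rates; point-mass distributions), not errors.
- Probabilistic draws that leave a ranged parameter's printed interval
  widen the stored interval rather than failing validation: the
  printed interval is sensitivity-analysis metadata, not a hard bound.

## Problem sizes

The shipped analyses use the study-scale settings throughout: the full
100,000-woman, 50-cycle cohort (a single run takes milliseconds, so no
scaling down is needed), all 27 strategies plus the comparator for the
frontier, 1,000 PSA iterations per comparison, and a full-size
(699,600-record) synthetic registry in the generator checks.

## Known limitations

- No pre-clinical natural history: screening benefit is entirely the
  stage shift at diagnosis, so the marginal value of extra screens
  scales with the number of screen-year incident cases; designs with
  long pre-clinical sojourn would value infrequent screening more.
- No overdiagnosis or indolent-DCIS modelling; every detected DCIS is
  treated.
- Transition probabilities between stages are time-homogeneous; only
  incidence and mortality are age-specific.
- False positives incur biopsy costs but no utility decrement.
- Costs are CNY at 2023 values with no inflation machinery; utilities
  and costs are societal-perspective point estimates.
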