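---
title: "Methods: estimating the economic burden of serious post-market ADRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the economic burden of serious post-market ADRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrburden)
```

## The problem

Randomized controlled trials (RCTs) are run under close supervision on
selected patients, so the adverse-drug-reaction (ADR) rates they report do
not always transfer to routine use. Spontaneous pharmacovigilance
databases, such as Canada Vigilance, capture ADRs as they occur in the
real world, but they come as raw report tables with no denominator and no
costing. `adrburden` turns such extracts into (i) exposure-normalized ADR
outcome rates comparable with pooled trial rates, and (ii) an annual
cost-of-illness estimate for serious ADR outcomes from three perspectives.
The shipped reference analysis covers the two TNF-α inhibitor biologics
infliximab (Remicade) and adalimumab (Humira) over 2014–2018.

## From report tables to a cohort

Extracts arrive as three delimited tables (reports, report–drug links,
outcome labels) sharing a `Report_ID`. `read_extract()` accepts the
`'$'`-delimited headerless dialect of public extracts and a CSV dialect;
ages reported in months or decades are normalized to years at read time,
and rows with unparseable dates are counted and reported, never silently
dropped. `join_and_dedup()` collapses exact duplicates; when duplicate
rows of one report disagree, the first non-missing value in file order
wins and the conflict is logged — the database documentation says only
that duplicates are removed, so this is our convention, recorded as such.

Cohort construction filters by case-insensitive substring match over all
drug names (combining brand-name spelling variants) regardless of the
suspect/concomitant role, and by inclusive calendar-year window on the
initial report date. Each report then receives raw outcome flags through a
configurable label dictionary and a single *primary* category by the
precedence **death > disability > hospitalization > OMIC > non-serious**.
Rates use the raw flags (a report may legitimately count under several
outcomes); costing uses the primary category so no report is costed twice.
The precedence order is configurable.

## Rates

The recipient denominator comes from sales: annual recipients = annual
sales ÷ average annual treatment cost ($29,500/year for infliximab,
$16,400/year for adalimumab). The point rate for an outcome over an
$n$-year window is

$$\hat r = \frac{\text{reports with the outcome}}{n \times \text{mean annual recipients}}.$$

Events are report counts, not patient counts, because the reference
analysis divides report counts by recipients. The "serious" row adds the
disability, hospitalization and OMIC flag counts (death excluded; a
switch includes it). Reported confidence intervals in this literature are
far wider than a binomial interval at these denominators, which indicates
between-year variation rather than binomial noise; the default CI is
therefore a t-interval (df = years − 1) over the annual rates, with a
Wilson interval as the option (and the fallback when only a pooled count
is available). The method used is recorded in the output.

RCT arm summaries (participants, all AEs, serious AEs, deaths per arm)
are pooled with a DerSimonian–Laird random-effects meta-analysis
implemented in the package on *untransformed* proportions: pooled rates
reported as "not significantly different from zero" can only arise on the
raw-proportion scale, so that scale is the default. Arms with zero or all
events get the standard 0.5/+1 continuity correction. `metafor` is used
in the test suite as an independent cross-check of the estimator, never
as the implementation.

## The cost model

All costs are 2018 CAD. Five-year category sums are divided by
`period_years` (5) to give annual averages. Only the four serious
categories are costed.

**Patient perspective (human capital).** A death at age $a$ forgoes
$\text{employment rate} \times \text{income}$ for each year from $a$ to
the working-age maximum (64), counting only years within the working-age
window 19–64, discounted at 1.5%/year with the first lost year
undiscounted:

$$L(a) = e \cdot y_{sex} \sum_{t \,:\, 19 \le a+t \le 64} (1+r)^{-t}.$$

Children ($a<19$) accrue from age 19 with discounting from the year of
death; ages above 64 contribute nothing. Disability uses the same annuity
with the annual loss scaled by the combined decrement
$1-(1-0.225)(1-0.315)$ (an additive variant is available; the choice is
recorded in run metadata). An optional offset subtracts the average
annual disability benefit ($11,506, floored at zero); it is off by
default because the reference base case lists the benefit among its
inputs without using it. Hospitalization costs one length-of-stay of
daily wages and OMIC one day; daily wage = annual income / 365 calendar
days (260 workdays available as an option).

**Unknown age and sex.** Unknown-age patients contribute the
drug-specific fraction assumed to be of working age (0.47 infliximab,
0.45 adalimumab) times the loss evaluated at the assumed age 52. Unknown
sex uses the sex-unknown average income ($46,268).

**Health-system perspective.** Direct costs only: a per-stay
hospitalization cost from an age-band schedule and $417 (one ER visit)
per OMIC event. The published source gives only the cost range
($1,766–$5,325), the stay range (1.2–3.9 days) and the
population-weighted averages ($4,205, 2.3 days); the five-band default
schedule in `default_hosp_bands()` is synthetic, spanning exactly those
endpoints, and unknown ages always use the published weighted averages.
Replace the schedule with the real file where available.

**Societal perspective (friction cost).** Direct costs plus the
productivity loss of replacing a displaced worker: 3 months of
employment-weighted wages per working-age death, scaled by the
employment decrement (0.225) for disability — only the displaced
fraction vacates a job — and zero for hospitalization and OMIC, whose
losses are typically made up later. By construction the societal total
equals the health-system total plus friction losses exactly, which the
tests assert.

**Disability horizon.** The reference analysis does not state whether
disability losses were accumulated annually or over the remaining working
life; this package accumulates them over the remaining working lifetime
(discounted, like deaths) and annualizes by `period_years`. This is our
documented convention, not an assertion about the original computation.

## Sensitivity analyses

One-way analysis re-runs the deterministic base case with one scalar
parameter at each bound (defaults: discount 0–3%, friction 1–5 months,
OMIC unit cost $208–$626).

The probabilistic analysis (default 5,000 iterations) draws
patient-level inputs per report from gamma distributions parameterized by
(mean, CV) with shape $1/CV^2$ and scale $mean \cdot CV^2$ — income,
hospitalization cost, length of stay, disability income loss — and
population-level inputs once per iteration from truncated normals —
employment rate, disability employment loss. Default dispersions were
calibrated once so each distribution's central 95% range approximates the
published probabilistic input ranges: income CV 0.11 (range
≈ $40,343–$61,181 around the sex-unknown mean), hospitalization cost CV
0.033, length-of-stay CV 0.033, disability income-loss CV 0.04,
employment sd 0.048 (≈ 64–83%), disability employment-loss sd 0.043
(≈ 15–32%). The published stay range for the probabilistic analysis
(2.6–2.9 days) sits above its own stated mean of 2.3 days; we calibrate
around the mean and note the discrepancy rather than reproduce it. Draws
of proportions are truncated to [0, 1]. Because the cost model is linear
in each drawn quantity separately and the draws are independent, the
Monte Carlo mean converges to the base case, which is the convergence
check the suite runs. All randomness is scoped: identical seeds give
bit-identical results, and the pipeline derives stage seeds from one root
seed recorded in the run metadata.

## The synthetic generator and its oracle

`generate_cvar()` emits the same three-table layout the reader consumes,
with exact duplicate rows injected at a configurable fraction and the
realized generating counts recorded as ground truth. Defaults mirror the
reference cohort's printed structure: outcome-flag marginals (death 1.2%,
disability 1.5%, hospitalization 27%, OMIC 65%), sex 58/36/6
female/male/unknown, a decadal age distribution peaking at 50–59 with
about half the known ages inside 19–64 plus an 8% unknown-age share, 96%
suspect labeling, 50% multi-drug reports and 2014–2018 dates.

Two realism caveats matter for interpreting green tests. First, flags
are drawn independently (death excluding disability), while real outcome
flags are strongly positively correlated — so the generator's realized
non-serious share is well above the reference cohort's 3%, and passing
tests say nothing about flag co-occurrence structure. Second, duplicates
are exact row copies; near-duplicate records with distinct ids (the hard
deduplication problem) are out of scope.

`expected_burden_oracle()` computes the expected annual cost per
category and perspective analytically: primary-category probabilities
follow from the flag scheme in closed form, and per-event unit costs are
averaged over the configured age and sex grids using explicit
year-by-year accumulation — deliberately sharing no code with the
pipeline's annuity, classification or aggregation path. Parameter
recovery is checked at n = 10,000 reports with a 5% per-cell tolerance.
That check uses a balanced configuration (each primary category ≈ 22–25%
of reports, ages 35–50) rather than the reference-like defaults: with
realistic marginals a 10,000-report cohort holds only ~120 deaths, whose
~10% binomial sampling noise would swamp a 5% band, so the balanced
fixture is the configuration under which the tolerance has statistical
meaning. A second check compares the oracle with the mean of 200
pipeline runs at n = 300 under reference-like mixed probabilities (3
standard errors).

## Numerical choices and degenerate inputs

* Discounting: first forgone year undiscounted ($t=0$), matching the
  annual-average framing; the annuity uses the closed geometric form and
  is verified against an explicit loop for every age 0–90, all three sex
  codes and rates {0, 1.5%, 3%}.
* Zero-variance PSA draws degenerate to the base case exactly (gamma and
  normal samplers return the mean when CV or sd is 0).
* Empty cohorts produce an all-zero breakdown; zero recipient
  denominators, non-positive treatment costs and negative ages raise
  domain errors; negative band costs are configuration errors.
* Rate CIs truncate at 0; meta-analysis CIs are truncated to [0, 1] for
  reporting while significance is judged on the untruncated lower bound.
* `users_estimate` rounds sales-derived recipients to whole patients per
  year before averaging.

## Problem sizes in the shipped checks

The test suite and reproduction script size their simulations for a
single CPU: oracle recovery at 10,000 reports, repeated-run convergence
at 200 × 300 reports, PSA determinism/zero-variance at a few hundred
reports, PSA convergence at 5,000 iterations on a 400-report cohort, and
interval-coverage sweeps over 20 generator seeds at 300 iterations each.

## Limitations

Spontaneous reports undercount non-serious ADRs and cannot establish
causality; rates computed here inherit both biases. The recipients
denominator is a sales-based approximation, not person-time on drug. The
published pooled RCT death rates for the reference drugs (0.01%, 0.04%)
cannot be re-derived without the original trial-arm appendix, so the
package treats trial arms as an input table and ships only the printed
pooled values as reference numbers. Full reproduction of the reference
burden totals requires the restricted report-level microdata and the
age-stratified hospitalization cost file; the package's validation
therefore rests on the printed-component arithmetic plus the synthetic
parameter-recovery checks described above.
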