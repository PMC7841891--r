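---
title: "Methods: a Markov cohort model for anticoagulation in atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for anticoagulation in atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afibcea)
```

## The decision problem and the model

Non-valvular atrial fibrillation (NVAF) patients on long-term
anticoagulation trade a lower ischemic stroke risk against bleeding risk
and drug cost. The package models four strategies — warfarin, rivaroxaban,
and dabigatran at 110 mg or 150 mg bid — with a discrete-time Markov cohort
model over four health states: event-free (`Min`), moderate disability
(`Mod`), severe disability (`Sev`) and death. The cycle length is one year
and the default horizon 30 years, long enough to capture essentially the
whole remaining lifetime of a typical NVAF cohort.

Within a cycle a patient experiences at most one of five competing events:
ischemic stroke (IS), intracranial hemorrhage (ICH), extracranial
hemorrhage (ECH), myocardial infarction (MI) or all-cause death. IS and ICH
outcomes follow a severity split (no sequelae / moderate / severe / fatal);
ECH and MI are either fatal or fully recovered. The model's structural
assumptions, taken as given: one event per cycle; time-constant transition
rates (no age trend); the severe state is irrecoverable and faces only
mortality; no treatment switching or discontinuation costs. All-cause
mortality enters as a competing risk alongside the events rather than being
applied multiplicatively after them, which keeps "one event per cycle"
literal and the transition rows exactly normalized.

## Accrual and discounting conventions

The source material for models of this kind frequently leaves accrual
details unstated, so the package fixes explicit conventions and exposes
flags for the genuinely ambiguous ones:

* A patient occupies one state for a whole cycle and transitions at cycle
  end. The cycle of a fatal event accrues the pre-event state's utility,
  and the event's acute cost is charged (`charge_fatal_event = TRUE` by
  default) — treatment of the acute event precedes death.
* Survivors of an event accrue, in the event cycle, the utility of their
  *destination* state; for ICH, ECH and MI that utility is multiplied by
  the event's within-cycle multiplier (0.80 / 0.80 / 0.84). The published
  utility table lists these values alongside the state utilities; they are
  read as multipliers rather than substitute utilities because a substitute
  ICH-year utility of 0.80 would exceed the event-free utility of 0.76.
  The multipliers apply for the event cycle only.
* The moderate state faces only all-cause mortality by default
  (`events_from_moderate = FALSE`), mirroring the explicit rule for the
  severe state; setting the flag lets moderate patients face the full event
  partition with severities that can only worsen.
* Discounting is 3\%/year for costs and effects, cycle $t$ weighted by
  $(1+r)^{-(t-1)}$ (first cycle undiscounted; `discount_first_cycle` flips
  the convention). No half-cycle correction is applied by default, as none
  is mentioned in the source analyses; `half_cycle_correction = TRUE`
  averages start- and end-of-cycle occupancy in the cohort accrual.
* `discount_rate_effects` can decouple the effect discount rate from the
  cost rate. This matters because the published 30-year QALY totals (e.g.
  15.46 for rivaroxaban with an event-free utility of 0.76) exceed the
  discounted-annuity ceiling $0.76 \sum_{t=1}^{30} 1.03^{-(t-1)} \approx
  15.34$, which implies the original analysis did not discount effects.
  The package's default discounts both; the acceptance analyses reproduce
  the published *orderings* with effects undiscounted rather than chasing
  the absolute totals, which the available description underdetermines.

The engine is validated two ways: against a closed-form two-state
(alive/dead) reduction, which it must match to $10^{-9}$, and against an
individual-level microsimulation built on the same per-cycle branch
decomposition, whose means must agree with the cohort run within Monte
Carlo error (the cohort model is the microsimulation's exact expectation).

## Parameters

All inputs ship as a YAML fixture (`inst/extdata/table1_base_case.yaml`)
and as `base_case_inputs()`: per-strategy annual event probabilities,
severity splits, case fatalities, annual treatment costs (drug +
monitoring + service; warfarin's 21 INR checks/year dominate its
monitoring cost), one-time event costs from national hospital-expense
statistics, and EQ-5D-style state utilities. Money is in US dollars, no
currency conversion. The aggregate annual-cost row of the source table is
taken as authoritative rather than recomputing unit price × dose ×
monitoring frequency, because the two disagree at the cent level; the unit
prices are documentation only. Parameters without a published plausible
range carry a degenerate range (low = base = high) and are held fixed in
both sensitivity analyses, matching the original analysis's practice of
varying only ranged parameters.

The willingness-to-pay threshold defaults to three times 2018 China GDP
per capita, $3 \times 9481.88 = 28445.64$ \$/QALY.

## Incremental analysis

Strategies are sorted by total cost; strictly dominated ones (costlier, no
more effective) are removed, then extended dominance is applied iteratively
until the frontier's consecutive ICERs strictly increase. Published
comparison tables report every strategy pairwise against warfarin rather
than a frontier ladder, so the CEA table carries both the
pairwise-vs-comparator increments and the frontier status/ICERs. Exact
ties are flagged `indifferent`, never divided and never dominated;
equal-QALY pairs return a dominance flag rather than a division result.
The recommended strategy maximizes net monetary benefit
$\mathrm{NMB} = \lambda E - C$, ties broken by lower cost then input order.
The classifier is property-tested against an exhaustive convex-blend
dominance oracle on random instances.

## Sensitivity analyses

**One-way (tornado).** Each ranged parameter is set to its lower and upper
bound with everything else at base, the full cohort model is re-run for
the reference/comparator pair (rivaroxaban vs warfarin by default) and the
ICER recorded; bars are sorted by swing. When a severity-split fraction is
varied, the other three fractions are rescaled proportionally so the split
keeps summing to one — the source is silent on this, and proportional
rescaling is the convention that preserves the split's composition.
Because the original model's internals are not reproducible from its
description, the package's tests assert the published tornado's
*directions* (ICER falls as warfarin's stroke or ICH risk or the
event-free utility rises; ICER rises with rivaroxaban's price), not its
printed values.

**Probabilistic.** Second-order Monte Carlo with 1,000 draws by default:
probabilities, severity fractions and utilities are drawn from beta
distributions, costs from log-normals, each fitted by the method of
moments with mean equal to the base case and standard deviation
(high − low)/3.92 — the published ranges are interpreted as 95% intervals,
the source naming only the distribution families
(`range_interpretation = "support"` switches to a uniform-width reading).
Severity splits are renormalized after drawing and the state-utility
ordering is restored by sorting; each sampled set must pass the full
validator, with up to 100 resampling attempts before erroring. Plausible
ranges are widened to cover each realized draw so the low ≤ base ≤ high
invariant remains meaningful on sampled sets. The deterministic engine
runs once per draw per strategy (no first-order noise). CEAC winner
counting splits exact ties equally, keeping each grid row summing to one.
The incremental cost-effectiveness plane ellipse is the normal-theory
mean-centered covariance ellipse at the $\chi^2_2$ quantile of the
requested coverage.

## Synthetic data

`generate_inputs()` emulates a literature-derived parameter table:
multiplicative log-normal jitter (default 10%, a realistic relative
uncertainty for trial-derived event rates) around the base case, truncated
into each parameter's legal domain, with splits renormalized, utilities
re-ordered and ranges regenerated around the perturbed values. It exists
to property-test the pipeline (every generated set must validate and run
end-to-end), not to mimic any real population; in particular it preserves
none of the correlation structure real trial estimates would have, so
passing tests demonstrate structural robustness, not clinical calibration.
`two_state_inputs()` collapses the model to constant-hazard survival for
the analytic oracle.

## Problem sizes and numerical choices

The shipped analyses use the model's own scale: 30 annual cycles, 1,000
PSA draws, 100,000 microsimulation patients for the cohort-agreement
check, 10,000 synthetic bivariate-normal draws for the ellipse-coverage
check, and 1,000 random instances for the dominance-oracle comparison.
Transition rows are required to sum to 1 within $10^{-12}$, occupancy rows
within $10^{-9}$; severity splits within $10^{-9}$; ICER ties use a
$10^{-9}$ absolute tolerance. Beta fits reject infeasible variances
($v \ge m(1-m)$); log-normal fits require a positive mean.

## Known limitations

No age-dependent background mortality, no treatment switching or
discontinuation, no ongoing disability-care costs beyond the annual
treatment cost (none are published), no correlated parameter sampling, no
EVPI, and no apixaban arm. Absolute cost/QALY totals depend on accrual
conventions the source does not fully specify; conclusions should rest on
the orderings, dominance structure and acceptability probabilities, which
are stable across those conventions.
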