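# afibcea

Decision-analytic cost-effectiveness modelling of oral anticoagulants for
stroke prevention in non-valvular atrial fibrillation (NVAF), for health
economists and outcomes researchers. The package compares four strategies —
adjusted-dose warfarin, rivaroxaban 20 mg qd, and dabigatran 110 mg / 150 mg
bid — with an annual-cycle Markov cohort model and reports incremental
cost-effectiveness, one-way (tornado) sensitivity analysis, and
probabilistic sensitivity analysis (PSA) with cost-effectiveness
acceptability curves (CEAC) and incremental cost-effectiveness plane
ellipses.

## The model

Patients start event-free (`Min`) and each year face a competing-event
partition: ischemic stroke (probability *p*<sub>IS</sub>), intracranial
hemorrhage (*p*<sub>ICH</sub>), extracranial hemorrhage (*p*<sub>ECH</sub>),
myocardial infarction (*p*<sub>MI</sub>), background all-cause death
(*p*<sub>D</sub>), or no event. Stroke and ICH outcomes follow severity
splits into no-sequelae, moderate disability (`Mod`), severe disability
(`Sev`, absorbing apart from death) or death; ECH and MI are fatal or fully
recovered. Costs are an annual treatment cost per strategy plus one-time
event costs; effectiveness is measured in quality-adjusted life-years
(QALYs) with state utilities *u*<sub>min</sub> ≥ *u*<sub>mod</sub> ≥
*u*<sub>sev</sub> and within-cycle multipliers for nonfatal ICH/ECH/MI.
Totals are discounted at 3%/year over a 30-year horizon.

Strategies are compared by the incremental cost-effectiveness ratio
ICER = ΔC/ΔE, with strict and extended dominance pruning of the frontier,
and by net monetary benefit NMB = λ·E − C at a willingness-to-pay threshold
λ = 3 × GDP per capita = $28,445.64/QALY. The PSA draws probabilities and
utilities from method-of-moments beta distributions and costs from
log-normal distributions fitted to each parameter's plausible range.

## Worked example

```r
library(afibcea)
inputs <- load_model_inputs(system.file("extdata", "table1_base_case.yaml",
                                        package = "afibcea"))
outcomes <- run_base_case(inputs)
incremental_analysis(outcomes, comparator = "warfarin",
                     wtp = inputs$config$wtp)
```

```
Cost-effectiveness comparison (comparator: warfarin | WTP 28445.64 $/QALY)
      strategy total_cost total_qaly delta_cost delta_qaly icer_vs_comparator
      warfarin    5046.93       8.19         NA         NA                 NA
 dabigatran110   23858.64       9.03   18811.70       0.84           22280.31
   rivaroxaban   29962.03      10.59   24915.10       2.40           10386.00
 dabigatran150   34518.18      10.41   29471.25       2.22           13277.41
 flag_vs_comparator               status frontier_icer      nmb
         comparator          on_frontier            NA 227925.1
               icer extendedly_dominated            NA 233130.6
               icer          on_frontier         10386 271248.5
               icer   strictly_dominated            NA 261593.3
Recommended at WTP: rivaroxaban
```

Warfarin is by far the cheapest strategy but yields the fewest QALYs;
rivaroxaban buys the most health and sits on the frontier at an ICER of
about $10,386 per QALY gained over warfarin — well under the threshold, so
it is the recommended strategy. Dabigatran 150 mg is strictly dominated
(costlier and less effective than rivaroxaban) and dabigatran 110 mg is
extendedly dominated. With effect discounting turned off
(`inputs$config$discount_rate_effects <- 0`) the QALY totals rise to
10.91 / 14.74 / 12.17 / 14.42 for warfarin / rivaroxaban / dabigatran 110 /
dabigatran 150, with the same orderings and dominance structure.

Uncertainty analyses:

```r
tor <- one_way_sensitivity(inputs)            # tornado over all ranged parameters
plot_tornado(tor, top = 10)
psa <- run_psa(sample_psa(inputs, n_draws = 1000, seed = 1))
plot_ceac(ceac(psa, seq(0, 60000, length.out = 61)))
plot_ice(ice_scatter(psa, "rivaroxaban", "warfarin"))
```

A command-line front end is installed at `inst/cli/afib-cea`
(`afib-cea base-case|owsa|psa --config FILE --out DIR ...`), writing CSVs,
PNG figures and a JSON run manifest.

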