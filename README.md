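# cdk46cea

A Markov cohort cost-effectiveness model of first-line treatment for
HR+/HER2− advanced breast cancer, comparing the three CDK4/6 inhibitors —
palbociclib, ribociclib and abemaciclib, each combined with letrozole —
against letrozole monotherapy from a healthcare-payer perspective (costs in
Qatari Riyal, QAR).

The package is for health-economics analysts who want a transparent,
scriptable re-implementation of this decision model: the cohort engine, the
incremental analysis, and the one-way sensitivity machinery are all plain R
functions over a declarative YAML input file, so every convention (discount
rate, half-cycle correction, discontinuation routing) is visible and
switchable.

## The model

Three health states — progression-free (PFS), progressed disease (PD),
death — with unidirectional transitions and, inside PFS, three dose tiers
(full dose, one and two toxicity-mandated reductions; tier hops move only
downward).  The cohort starts in full-dose PFS and is iterated over 120
one-month cycles.  Per cycle *k*, with one-cycle kernel **P** and occupancy
row **x**ₖ = **x**ₖ₋₁**P**, the model accrues

- cost: `(1+r)^(−k/12) · ĉₖ · C`, and
- QALYs: `(1+r)^(−k/12) · ĉₖ · u / 12`,

where `ĉₖ = (xₖ₋₁ + xₖ)/2` is the half-cycle-corrected credit, `C` the
per-cycle state costs, `u` the state utilities (PFS utility is a mixture
over grade-3/4 adverse-event states), and `r = 0.03` the annual discount
rate.  Strategies are compared by the incremental cost-effectiveness ratio
`ICER = ΔC/ΔE` against a willingness-to-pay threshold of 448,785 QAR/QALY,
with dominance classified when one arm is both cheaper and more effective.

## Worked example

```r
library(cdk46cea)
inputs  <- load_inputs(cdk46_example("table1_base_case.yaml"))
results <- run_model(inputs)
lt <- league_table(results, wtp = inputs$settings$wtp)
lt$arms
#>   arm         total_cost pfs_cost pd_cost total_qaly pfs_qaly pd_qaly
#> 1 palbociclib     930452   762956  167496     4.3998   2.4038  1.9960
#> 2 ribociclib      781615   632218  149397     4.4421   2.6618  1.7803
#> 3 abemaciclib     653544   481120  172423     4.2686   2.2139  2.0547
#> 4 letrozole       101216    53899   47317     2.1385   1.5747  0.5639
lt$comparisons[, c("intervention", "comparator", "icer", "decision")]
#>   intervention comparator    icer decision
#> 1 palbociclib  letrozole   366714 cost_effective
#> 2 ribociclib   letrozole   295366 cost_effective
#> 3 abemaciclib  letrozole   259294 cost_effective
#> 4 ribociclib   palbociclib     NA dominant
#> 5 palbociclib  abemaciclib 2111522 not_cost_effective
#> 6 ribociclib   abemaciclib  738355 not_cost_effective
```

Reading: every CDK4/6-plus-letrozole arm is cost-effective against
letrozole alone at the 448,785 QAR/QALY threshold; ribociclib dominates
palbociclib (cheaper and more effective); and ribociclib's extra QALYs over
abemaciclib cost more per QALY than the threshold allows, so abemaciclib is
the preferred of the two.  These are the same four decision classes the
published analysis reports.

Sensitivity analysis and threshold search:

```r
spec <- load_dsa_spec(cdk46_example("dsa_ribociclib_vs_palbociclib.yaml"))
dsa  <- run_dsa(inputs, spec$parameters, spec$comparison)
table(dsa$conclusion)

thr <- threshold_search(inputs, "arms.palbociclib.costs.tier0",
                        c("ribociclib", "palbociclib"),
                        lo = 0.5, hi = 1.0, scale = "factor")
thr$cutoff  # palbociclib full-dose cycle cost at which the preferred arm flips
```

A thin command-line wrapper over the same functions ships at
`inst/cli/cdk46cea.R` (`run`, `dsa`, `tornado`, `threshold` subcommands).

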