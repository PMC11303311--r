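---
title: "Model and methods: a within-cycle-corrected Markov cohort CEA of CDK4/6 inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a within-cycle-corrected Markov cohort CEA of CDK4/6 inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdk46cea)
```

## The decision problem

First-line treatment of hormone-receptor-positive, HER2-negative advanced
breast cancer combines a CDK4/6 inhibitor (palbociclib, ribociclib or
abemaciclib) with letrozole, or uses letrozole alone.  The inhibitors
lengthen progression-free survival but carry high acquisition costs and
grade-3/4 toxicities that force dose reductions.  `cdk46cea` implements a
deterministic Markov cohort model of this choice from a healthcare-payer
perspective, with costs in Qatari Riyal (QAR) and effectiveness in
quality-adjusted life years (QALYs), and compares strategies through
incremental cost-effectiveness ratios (ICERs) against a willingness-to-pay
(WTP) threshold of 448,785 QAR per QALY (1.5 times GDP per capita; a
variant figure of 448,758 also circulates in summaries of the source study
— the Methods value is used here).

## Model structure

Three health states: progression-free (PFS), progressed disease (PD),
death.  Transitions are unidirectional (PFS to PD or death; PD to death;
death absorbing).  Within PFS, CDK4/6 arms carry three dose tiers — full
dose, one reduction, two reductions — entered at full dose; grade-3/4
toxicity forces stepwise tier descent, tier 0 to tier 1 with the monthly
one-level reduction probability and tier 1 to tier 2 with the two-level
probability.  Tiers only move downward and direct two-tier jumps within a
cycle are not modelled.  The letrozole arm has a single tier and no
reductions.

The cohort starts entirely in the full-dose PFS state and is iterated over
120 one-month cycles (10 years).  Per cycle, costs accrue as occupancy
times the state's per-cycle cost (tier-specific drug acquisition plus
monitoring in PFS; second-line treatment cost in PD), and QALYs as
occupancy times the state utility divided by 12.

**Within-cycle correction.** Transitions happen continuously, not at cycle
boundaries, so crediting either boundary's occupancy biases person-time.
The default (`wcc_method = "half_cycle"`) credits the trapezoidal average
of the start- and end-of-cycle occupancy rows; `"none"` credits
end-of-cycle occupancy.  A property test verifies the half-cycle totals
always lie between pure start- and end-of-cycle crediting.

**Discounting.** Costs and effects are discounted at
`(1 + r)^(-k/12)` for cycle `k` (end-of-cycle timing).  The source study
does not state its discount rate; the package's base case uses the
conventional 3% per year, which also reproduces the study's letrozole-arm
cost most closely among the candidates 0%, 3% and 3.5% (101,216 QAR vs the
published 100,855; the three candidates give 109,867 / 101,216 / 99,904
QAR and 2.304 / 2.139 / 2.113 QALYs against the published 2.093).  The
rate is a plain `model_settings()` argument.

**Adverse events and utilities.** Grade-3/4 neutropenia, diarrhea and
hepatotoxicity carry absolute health-state utilities (0.72, 0.70, 0.77).
The per-cycle PFS utility is the mutually-exclusive mixture
`u_eff = (1 - sum(p_j)) u_pfs + sum(p_j u_j)` over the utility-bearing
events with monthly incidences `p_j`; mutual exclusivity is a second-order
approximation justified by the small monthly incidences.  QTc-prolongation
events carry no utility entry and never enter QALY weighting; they are in
the input schema for completeness.  PD uses a shared utility of 0.505 and
death 0.

**Discontinuation routing.** The published model narrative sends patients
who discontinue for toxicity to next-line treatment, which lives in the PD
state; the published base-case results, however, are only consistent with
discontinuation *not* moving state occupancy.  With discontinuers routed to
PD the modelled CDK-arm totals fall 10–16% below the published ones and the
QALY ordering of ribociclib and palbociclib inverts, overturning every
published pairwise conclusion; with discontinuers remaining in their PFS
tier the palbociclib and abemaciclib arms reproduce within about 1%, the
ribociclib QALYs within 0.4%, and all four published base-case decision
classes reproduce.  `disc_routing = "stay"` is therefore the default and
`"pd"` the selectable alternative; the choice is a `model_settings`
argument and both conventions are validated and tested.

**Rate–probability calculus.** Trial-derived cumulative probabilities are
converted to constant hazards (`r = -log(1-p)/t`) and back to fixed-time
monthly probabilities (`p = 1 - exp(-rt)`); `split_death_prob()` divides
all-cause death between background incidence (13%) and progression (87%)
on the hazard scale, where the fractions partition the total hazard
exactly.  Because trial reports do not say which scale the published split
used, a probability-scale mode is also provided; the packaged inputs
already contain the split per-state death probabilities, so this calculus
is only needed when users derive new arms.

## Input data

All inputs ship as a flat, versioned YAML fixture
(`cdk46_example("table1_base_case.yaml")`): per-cycle tier costs, the
shared PD cycle cost (3,531.52 QAR), PFS/PD/adverse-event utilities, and
monthly transition, dose-reduction, discontinuation and adverse-event
probabilities for all four arms, entered verbatim from the published input
table.  Two entries are kept as printed although they look like
transcription artifacts — the palbociclib 75 mg tier cost equals the
125 mg cost, and all three abemaciclib tiers share one cost — since the
cost sensitivity analysis covers them.  Validation is diagnostic-based
(`validate_arm()` returns structured field/rule/value records) and
enforces probability ranges, utility positivity, tier structure and
per-tier outflow feasibility; infeasible kernels are refused, never
renormalised.

## Comparison rules

`compare_arms()` classifies an ordered pair: dominant (cheaper, more
effective), dominated, equal (differences under 1e-9 QALYs / 1e-6 QAR,
i.e. below any reporting precision), or an ICER quadrant.  In the
cheaper-but-less-effective quadrant the ICER is reported from the costlier
arm's perspective and the cost-saving option is preferred iff that ICER
exceeds the WTP.  `league_table()` reports each non-reference arm against
the reference and each remaining pair once, from the more effective arm's
perspective — the published layout.  Internal arithmetic is full
precision; reports round to whole QAR and 4-decimal QALYs.

On the published per-arm totals this layer reproduces the published ICERs
(362,120; 334,170; 1,588,545 QAR/QALY exactly; the
abemaciclib-vs-letrozole quotient of the printed totals rounds to 256,439,
one riyal above the printed 256,438, because the printed totals are
themselves rounded) and the dominance of ribociclib over palbociclib.

## Sensitivity analysis

`run_dsa()` moves one parameter at a time to its bounds — costs ±15%,
utilities and probabilities ±10%, or published confidence-interval bounds
— re-runs the model and compares decisions; probability parameters with
base values under 1% are excluded.  A parameter is *robust* when the
preferred strategy at the WTP is unchanged at both bounds (the published
tables use the same convention: rows where a dominance relation relaxes
into a beyond-threshold ICER are still labelled robust, with a caveat);
the narrative field carries such caveats.  Perturbed probabilities are
clipped to [0,1] with a loud diagnostic, never silently.
`threshold_search()` bisects a bracket to a 1e-6 relative tolerance and
verifies the conclusion flip by evaluating both sides of the cutoff.
`tornado()` ranks parameters by the ICER span across their bounds,
flagging bounds where the comparison becomes dominant/dominated rather
than inventing an ICER; ordering is invariant under permutation of the
parameter list (ties break on labels).

Packaged sensitivity specifications mirror the published one-way analyses
for ribociclib-vs-palbociclib and ribociclib-vs-abemaciclib.  On the
modelled base case all published *robust* rows of the
ribociclib-vs-palbociclib table reproduce.  The published conclusion
*flips* (ribociclib cost +15%, palbociclib cost −15%) and a handful of
near-threshold ribociclib-vs-abemaciclib rows do not reproduce, because
they hinge on the ribociclib arm's absolute cost: the published
sensitivity table is internally inconsistent with the published base-case
table — its implied discounted tier-0 and tier-1 occupancies (36.6 and
11.7 months) sum to more than the 41.4 discounted PFS months any
unidirectional cascade admits — so no parameterisation of this model class
can match both.  The package keeps the printed inputs and the stepwise
tier semantics and reports its own sensitivity conclusions.

## Synthetic scenarios and testing strategy

`gen_random_arm()` samples always-valid arms (costs log-uniform on
[500, 50,000] QAR, utilities uniform on (0.3, 0.95], transition
probabilities uniform on [0, 0.1], adverse-event incidences on [0, 0.06])
— ranges bracketing the base case by roughly an order of magnitude either
way — reproducibly from an explicit seed and without touching the
caller's RNG state.  `gen_closed_form_scenario()` returns degenerate
inputs with analytic totals (immortal full health: exactly 10 QALYs;
two-state geometric decay: the geometric-series person-time; a single
hand-computable cycle), which the engine must match to 1e-9 relative
error.  The test suite adds an independent individual-level
microsimulation oracle (2×10^5 simulated patients per arm, fixed seeds,
agreement within 3 Monte-Carlo standard errors), chosen large enough to
detect crediting or discounting errors while keeping the default suite
fast.

What passing these tests shows — and does not show.  The synthetic
generator emulates the *structure* the analysis assumes (valid probability
vectors, positive costs, utilities in (0,1]); it does not emulate
correlated parameter uncertainty, time-varying hazards, or real-world
adherence, so green properties certify the engine's arithmetic, not the
clinical realism of any particular input set.

## Known limitations

* Constant monthly transition probabilities; no time-varying hazards or
  tunnel states.
* No probabilistic sensitivity analysis (the source analysis performed
  none); one-way DSA only.
* No efficiency-frontier or net-monetary-benefit ranking; pairwise
  comparisons only.
* The published study's own tables are mutually inconsistent in places
  (see above); exact reproduction of the ribociclib arm's cost is
  impossible in principle and the model's ribociclib total (about 782k
  QAR) sits below the published 880k, with all base-case decision classes
  nevertheless reproducing.

## Worked example

```{r example, eval = FALSE}
inputs <- load_inputs(cdk46_example("table1_base_case.yaml"))
results <- run_model(inputs)
league_table(results, wtp = inputs$settings$wtp)$comparisons

spec <- load_dsa_spec(cdk46_example("dsa_ribociclib_vs_palbociclib.yaml"))
dsa <- run_dsa(inputs, spec$parameters, spec$comparison)
tornado(inputs, spec$parameters, spec$comparison)
```
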