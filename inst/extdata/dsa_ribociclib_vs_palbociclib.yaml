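# One-way sensitivity parameters for the ribociclib-vs-palbociclib
# comparison: costs varied +/-15%, utilities and transition probabilities
# +/-10% (or published confidence-interval bounds where available).
# Probability parameters with base values below 0.01 are excluded by the
# analysis itself.
comparison:
  intervention: ribociclib
  comparator: palbociclib
parameters:
  - path: arms.palbociclib.costs.tier0
    label: "Palbociclib 125 mg cycle cost (full dose)"
    mode: percent
    low: -15
    high: 15
  - path: arms.palbociclib.costs.tier1
    label: "Palbociclib 100 mg cycle cost (1-level reduction)"
    mode: percent
    low: -15
    high: 15
  - path: arms.ribociclib.costs.tier0
    label: "Ribociclib 600 mg cycle cost (full dose)"
    mode: percent
    low: -15
    high: 15
  - path: arms.ribociclib.costs.tier1
    label: "Ribociclib 400 mg cycle cost (1-level reduction)"
    mode: percent
    low: -15
    high: 15
  - path: arms.palbociclib.utilities.pfs
    label: "Utility of PFS (palbociclib)"
    mode: absolute_bounds
    low: 0.7387
    high: 0.7627
  - path: arms.ribociclib.utilities.pfs
    label: "Utility of PFS (ribociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.*.utilities.pd
    label: "Utility of PD (all arms)"
    mode: absolute_bounds
    low: 0.45
    high: 0.55
  - path: arms.*.utilities.ae.neutropenia_g34
    label: "Utility of grade 3/4 neutropenia (all arms)"
    mode: percent
    low: -10
    high: 10
  - path: arms.palbociclib.probabilities.prog
    label: "PFS to PD (palbociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.prog
    label: "PFS to PD (ribociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.palbociclib.probabilities.reduce1
    label: "Dose reduction by 1 level (palbociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.reduce1
    label: "Dose reduction by 1 level (ribociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.palbociclib.probabilities.ae.neutropenia_g34
    label: "Grade 3/4 neutropenia incidence (palbociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.ae.neutropenia_g34
    label: "Grade 3/4 neutropenia incidence (ribociclib)"
    mode: percent
    low: -10
    high: 10
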