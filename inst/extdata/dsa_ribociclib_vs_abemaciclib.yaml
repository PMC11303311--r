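# One-way sensitivity parameters for the ribociclib-vs-abemaciclib
# comparison: costs +/-15%, utilities and transition probabilities +/-10%
# or published confidence-interval bounds.
comparison:
  intervention: ribociclib
  comparator: abemaciclib
parameters:
  - path: arms.abemaciclib.costs.tier0
    label: "Abemaciclib 150 mg BID cycle cost (full dose)"
    mode: percent
    low: -15
    high: 15
  - path: arms.abemaciclib.costs.tier1
    label: "Abemaciclib 100 mg BID cycle cost (1-level reduction)"
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
  - path: arms.abemaciclib.utilities.pfs
    label: "Utility of PFS (abemaciclib)"
    mode: percent
    low: -10
    high: 10
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
  - path: arms.*.utilities.ae.diarrhea_g34
    label: "Utility of grade 3/4 diarrhea and GI events (all arms)"
    mode: percent
    low: -10
    high: 10
  - path: arms.abemaciclib.probabilities.prog
    label: "PFS to PD (abemaciclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.prog
    label: "PFS to PD (ribociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.abemaciclib.probabilities.reduce1
    label: "Dose reduction by 1 level (abemaciclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.reduce1
    label: "Dose reduction by 1 level (ribociclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.abemaciclib.probabilities.ae.neutropenia_g34
    label: "Grade 3/4 neutropenia incidence (abemaciclib)"
    mode: percent
    low: -10
    high: 10
  - path: arms.ribociclib.probabilities.ae.neutropenia_g34
    label: "Grade 3/4 neutropenia incidence (ribociclib)"
    mode: percent
    low: -10
    high: 10
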