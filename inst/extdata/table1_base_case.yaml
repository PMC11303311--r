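# Base-case model inputs: published per-cycle costs (QAR), utilities and
# monthly transition probabilities for the four first-line strategies.
# Values are entered exactly as printed in the source cost study.
schema_version: 1
settings:
  horizon_cycles: 120
  cycle_length_months: 1
  annual_discount_rate: 0.03
  wcc_method: half_cycle
  wtp: 448785            # 1.5 x GDP per capita (QAR per QALY)
  currency: QAR
  disc_routing: stay
arms:
  - name: palbociclib
    costs:
      tier0: 20215.75    # 125 mg full dose
      tier1: 18503.83    # 100 mg, one dose reduction
      tier2: 20215.75    # 75 mg, as printed (identical to tier0; plausibly a
                         # transcription artifact in the source, kept verbatim)
      pd: 3531.52
    utilities:
      pfs: 0.7507
      pd: 0.505
      ae:
        neutropenia_g34: 0.72
        diarrhea_g34: 0.70
        hepatotox_g3: 0.77
        hepatotox_g4: 0.77
    probabilities:
      prog: 0.0211
      pfs_death: 0.000779
      pd_death: 0.0067
      reduce1: 0.0107
      reduce2: 0.0066
      disc: 0.0044
      ae:
        neutropenia_g34: 0.04636
        diarrhea_g34: 0.0009
        hepatotox_g3: 0.0
        hepatotox_g4: 0.0
        qtc_480_500: 0.0
        qtc_gt_500: 0.0
  - name: ribociclib
    costs:
      tier0: 19068.16    # 600 mg full dose
      tier1: 13578.97    # 400 mg
      tier2: 8089.78     # 200 mg
      pd: 3531.52
    utilities:
      pfs: 0.774
      pd: 0.505
      ae:
        neutropenia_g34: 0.72
        diarrhea_g34: 0.70
        hepatotox_g3: 0.77
        hepatotox_g4: 0.77
    probabilities:
      prog: 0.0195
      pfs_death: 0.00031
      pd_death: 0.0091
      reduce1: 0.027
      reduce2: 0.014
      disc: 0.0051
      ae:
        neutropenia_g34: 0.05934
        diarrhea_g34: 0.002
        hepatotox_g3: 0.0051
        hepatotox_g4: 0.0012
        qtc_480_500: 0.002
        qtc_gt_500: 0.0002
  - name: abemaciclib
    costs:
      tier0: 13478.67    # 150 mg BID full dose (all tiers share one printed cost)
      tier1: 13478.67    # 100 mg BID
      tier2: 13478.67    # 50 mg BID
      pd: 3531.52
    utilities:
      pfs: 0.745
      pd: 0.505
      ae:
        neutropenia_g34: 0.72
        diarrhea_g34: 0.70
        hepatotox_g3: 0.77
        hepatotox_g4: 0.77
    probabilities:
      prog: 0.0222
      pfs_death: 0.00191
      pd_death: 0.0058
      reduce1: 0.0183
      reduce2: 0.0092
      disc: 0.0121
      ae:
        neutropenia_g34: 0.01323
        diarrhea_g34: 0.0122
        hepatotox_g3: 0.0034
        hepatotox_g4: 0.0034
        qtc_480_500: 0.0
        qtc_gt_500: 0.0
  - name: letrozole
    reference: true
    costs:
      tier0: 2082.25     # letrozole 2.5 mg monotherapy, single dose tier
      pd: 3531.52
    utilities:
      pfs: 0.73
      pd: 0.505
      ae:
        neutropenia_g34: 0.72
        diarrhea_g34: 0.70
        hepatotox_g3: 0.77
        hepatotox_g4: 0.77
    probabilities:
      prog: 0.0302
      pfs_death: 0.0049
      pd_death: 0.056
      reduce1: 0.0
      reduce2: 0.0
      disc: 0.0
      ae:
        neutropenia_g34: 0.00059
        diarrhea_g34: 0.0012
        hepatotox_g3: 0.0008
        hepatotox_g4: 0.0
        qtc_480_500: 0.0
        qtc_gt_500: 0.0
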