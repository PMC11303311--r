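# Shared fixtures: the packaged base case, and small hand-built inputs for
# closed-form checks.

base_inputs <- function() {
  load_inputs(cdk46_example("table1_base_case.yaml"))
}

# Minimal single-tier arm with no adverse events.
toy_arm <- function(name, cost = 1000, pd_cost = 500, u_pfs = 0.8,
                    u_pd = 0.5, prog = 0.02, pfs_death = 0.01,
                    pd_death = 0.05) {
  treatment_arm(
    name,
    costs = list(tier0 = cost, pd = pd_cost),
    utilities = list(pfs = u_pfs, pd = u_pd, ae = list()),
    probabilities = list(prog = prog, pfs_death = pfs_death,
                         pd_death = pd_death, reduce1 = 0, reduce2 = 0,
                         disc = 0,
                         ae = list(neutropenia_g34 = 0, diarrhea_g34 = 0,
                                   hepatotox_g3 = 0, hepatotox_g4 = 0,
                                   qtc_480_500 = 0, qtc_gt_500 = 0))
  )
}

# Two-arm input set for a one-cycle linear model where arm costs enter
# totals linearly: deathless, progression-free, end-of-cycle credit, no
# discounting, so total_cost(arm) == cycle cost and total_qaly == u / 12.
linear_toy_inputs <- function(cost_a = 1000, cost_b = 800, u_a = 0.9,
                              u_b = 0.6, wtp = 12000) {
  arms <- list(
    A = toy_arm("A", cost = cost_a, u_pfs = u_a, prog = 0, pfs_death = 0,
                pd_death = 0),
    B = toy_arm("B", cost = cost_b, u_pfs = u_b, prog = 0, pfs_death = 0,
                pd_death = 0)
  )
  structure(
    list(settings = model_settings(horizon_cycles = 1L,
                                   annual_discount_rate = 0,
                                   wcc_method = "none", wtp = wtp),
         arms = arms, reference = "B", schema_version = 1L),
    class = "cea_inputs"
  )
}
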