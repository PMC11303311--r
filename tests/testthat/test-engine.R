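# Cohort engine: kernel construction, trace mechanics, accumulation.

test_that("transition rows follow the printed inputs by hand arithmetic", {
  inputs <- base_inputs()
  P <- build_transition_matrix(inputs$arms$letrozole, inputs$settings)
  expect_identical(colnames(P), c("PFS_T0", "PD", "DEAD"))
  expect_equal(unname(P["PFS_T0", ]),
               c(1 - 0.0302 - 0.0049, 0.0302, 0.0049), tolerance = 1e-15)
  expect_equal(unname(P["PD", ]), c(0, 1 - 0.056, 0.056), tolerance = 1e-15)
  expect_equal(unname(P["DEAD", ]), c(0, 0, 1))

  # CDK arm: five states, downward tier hops only
  Pr <- build_transition_matrix(inputs$arms$ribociclib, inputs$settings)
  expect_identical(colnames(Pr),
                   c("PFS_T0", "PFS_T1", "PFS_T2", "PD", "DEAD"))
  expect_identical(unname(Pr["PFS_T0", "PFS_T1"]), 0.027)
  expect_identical(unname(Pr["PFS_T1", "PFS_T2"]), 0.014)
  expect_identical(unname(Pr["PFS_T2", "PFS_T1"]), 0)
  expect_identical(unname(Pr["PD", "PFS_T0"]), 0)

  # routing convention moves discontinuation into the PD column
  Ppd <- build_transition_matrix(inputs$arms$ribociclib,
                                 model_settings(disc_routing = "pd"))
  expect_equal(unname(Ppd["PFS_T0", "PD"]), 0.0195 + 0.0051,
               tolerance = 1e-15)
  expect_equal(unname(Pr["PFS_T0", "PD"]), 0.0195, tolerance = 1e-15)
})

test_that("every kernel row is stochastic and infeasible arms are refused", {
  inputs <- base_inputs()
  for (routing in c("stay", "pd")) {
    s <- model_settings(disc_routing = routing)
    for (arm in inputs$arms) {
      P <- build_transition_matrix(arm, s)
      expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
  }

  frozen <- toy_arm("still", prog = 0, pfs_death = 0, pd_death = 0)
  expect_equal(build_transition_matrix(frozen), diag(3), ignore_attr = TRUE)

  over <- base_inputs()$arms$letrozole
  over$probabilities$prog <- 0.6
  over$probabilities$pfs_death <- 0.3
  over$probabilities$disc <- 0.2
  expect_error(
    build_transition_matrix(over, model_settings(disc_routing = "pd")),
    "tier 0 outflow"
  )
})

test_that("effective utility mixes adverse-event states into PFS", {
  inputs <- base_inputs()
  expect_identical(effective_cycle_utility(toy_arm("plain", u_pfs = 0.8),
                                           "PFS_T0"), 0.8)
  expect_identical(effective_cycle_utility(inputs$arms$palbociclib, "PD"),
                   0.505)
  expect_identical(effective_cycle_utility(inputs$arms$palbociclib, "DEAD"),
                   0)
  # hand evaluation of the mixture for palbociclib (hepatotoxicity and QTc
  # incidences are zero in that arm)
  hand <- (1 - 0.04636 - 0.0009) * 0.7507 + 0.04636 * 0.72 + 0.0009 * 0.70
  expect_equal(effective_cycle_utility(inputs$arms$palbociclib, "PFS_T0"),
               hand, tolerance = 1e-12)
  expect_error(effective_cycle_utility(inputs$arms$palbociclib, "PFS_T9"),
               "unknown state")
})

test_that("the trace conserves mass and is unidirectional", {
  inputs <- base_inputs()
  for (arm in inputs$arms) {
    tr <- run_trace(arm, inputs$settings)
    expect_equal(rowSums(tr$occupancy), rep(1, 121), tolerance = 1e-10,
                 ignore_attr = TRUE)
    dead <- tr$occupancy[, "DEAD"]
    expect_true(all(diff(dead) >= -1e-12))
    pfs <- rowSums(tr$occupancy[, grep("^PFS_", tr$states), drop = FALSE])
    expect_true(all(diff(pfs) <= 1e-12))
  }
  tr <- run_trace(inputs$arms$letrozole, inputs$settings)
  expect_equal(unname(tr$occupancy[2, ]), c(0.9649, 0.0302, 0.0049),
               tolerance = 1e-12)
})

test_that("closed-form scenarios are reproduced to 1e-9 relative error", {
  sc <- gen_closed_form_scenario("immortal_full_health")
  res <- run_arm(sc$arm, sc$settings)
  expect_equal(res$total_qaly, sc$expected$total_qaly, tolerance = 1e-9)
  expect_equal(res$total_cost, sc$expected$total_cost, tolerance = 1e-9)

  for (q in c(0.01, 0.05, 0.2)) {
    sc <- gen_closed_form_scenario("two_state_geometric", q = q)
    res <- run_arm(sc$arm, sc$settings)
    expect_equal(res$total_cost, sc$expected$total_cost, tolerance = 1e-9)
    expect_equal(res$total_qaly, sc$expected$total_qaly, tolerance = 1e-9)
  }

  sc <- gen_closed_form_scenario("single_cycle")
  res <- run_arm(sc$arm, sc$settings)
  expect_equal(res$total_cost, sc$expected$total_cost, tolerance = 1e-12)
  expect_equal(res$total_qaly, sc$expected$total_qaly, tolerance = 1e-12)
})

test_that("accumulation is additive across state groups and linear in costs", {
  inputs <- base_inputs()
  for (arm in inputs$arms) {
    res <- run_arm(arm, inputs$settings)
    expect_equal(res$total_cost, res$pfs_cost + res$pd_cost,
                 tolerance = 0.01 / max(res$total_cost, 1))
    expect_equal(res$total_qaly, res$pfs_qaly + res$pd_qaly,
                 tolerance = 1e-9)
  }

  arm <- inputs$arms$ribociclib
  doubled <- arm
  for (f in names(doubled$costs)) doubled$costs[[f]] <- 2 * doubled$costs[[f]]
  expect_equal(run_arm(doubled, inputs$settings)$total_cost,
               2 * run_arm(arm, inputs$settings)$total_cost,
               tolerance = 1e-12)

  free <- arm
  for (f in names(free$costs)) free$costs[[f]] <- 1e-9
  expect_lt(run_arm(free, inputs$settings)$total_cost, 1e-6)
})

test_that("half-cycle totals sit between start- and end-of-cycle crediting", {
  inputs <- base_inputs()
  for (arm in inputs$arms[c("letrozole", "ribociclib")]) {
    half <- run_arm(arm, inputs$settings)
    none <- run_arm(arm, model_settings(wcc_method = "none"))
    # start-of-cycle crediting, assembled from the trace by hand
    tr <- half$trace
    costs <- cdk46cea:::state_cycle_costs(arm)
    start_cost <- sum(tr$discount *
                        as.vector(tr$occupancy[-121, ] %*% costs))
    expect_lt(none$total_cost, half$total_cost)
    expect_lt(half$total_cost, start_cost)
    expect_equal(half$total_cost, (none$total_cost + start_cost) / 2,
                 tolerance = 1e-12)
  }
})

test_that("discounting strictly shrinks totals as the rate rises", {
  inputs <- base_inputs()
  for (arm in inputs$arms[c("letrozole", "palbociclib")]) {
    res <- lapply(c(0, 0.015, 0.03, 0.1), function(r) {
      run_arm(arm, model_settings(annual_discount_rate = r))
    })
    costs <- vapply(res, `[[`, numeric(1), "total_cost")
    qalys <- vapply(res, `[[`, numeric(1), "total_qaly")
    expect_true(all(diff(costs) < 0))
    expect_true(all(diff(qalys) < 0))
  }
})

test_that("trace export carries occupancy and cumulative accrual", {
  inputs <- base_inputs()
  res <- run_arm(inputs$arms$letrozole, inputs$settings)
  tab <- trace_table(res$trace)
  expect_identical(nrow(tab), 121L)
  expect_identical(tab$cycle[1], 0L)
  expect_equal(tab$cum_cost[121], res$total_cost, tolerance = 1e-9)
  expect_equal(tab$cum_qaly[121], res$total_qaly, tolerance = 1e-9)
})
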