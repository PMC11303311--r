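# One-way DSA, threshold search and tornado mechanics.

test_that("perturbation is targeted, pure, and clips probabilities loudly", {
  inputs <- base_inputs()
  same <- perturb_inputs(inputs, "arms.ribociclib.costs.tier0", factor = 1)
  expect_equal(same$arms, inputs$arms, tolerance = 0)

  up <- perturb_inputs(inputs, "arms.ribociclib.costs.tier0", factor = 1.15)
  expect_equal(up$arms$ribociclib$costs$tier0, 21928.384, tolerance = 1e-12)
  # original untouched, other fields untouched
  expect_identical(inputs$arms$ribociclib$costs$tier0, 19068.16)
  expect_identical(up$arms$ribociclib$costs$tier1, 13578.97)

  expect_warning(
    clipped <- perturb_inputs(inputs, "arms.letrozole.probabilities.pd_death",
                              factor = 20),
    "clipped"
  )
  expect_identical(clipped$arms$letrozole$probabilities$pd_death, 1)

  # wildcard fans out over every arm
  pd <- perturb_inputs(inputs, "arms.*.utilities.pd", value = 0.45)
  for (arm in pd$arms) expect_identical(arm$utilities$pd, 0.45)

  expect_error(perturb_inputs(inputs, "arms.nosucharm.costs.tier0",
                              factor = 2), "cannot resolve")
  expect_error(perturb_inputs(inputs, "arms.letrozole.costs.tier0"),
               "exactly one")
})

test_that("a vanishing perturbation is robust and reproduces the base case", {
  inputs <- base_inputs()
  params <- list(dsa_parameter("arms.ribociclib.costs.tier0", "percent",
                               low = -1e-9, high = 1e-9))
  dsa <- run_dsa(inputs, params, c("ribociclib", "palbociclib"))
  base <- attr(dsa, "base")
  expect_identical(dsa$conclusion, "robust")
  expect_equal(dsa$delta_cost_low, base$delta_cost, tolerance = 1e-6)
  expect_equal(dsa$delta_cost_high, base$delta_cost, tolerance = 1e-6)
  expect_identical(dsa$decision_low, base$decision_at_wtp)
})

test_that("rare-event probability parameters are excluded from the DSA", {
  inputs <- base_inputs()
  params <- list(
    dsa_parameter("arms.palbociclib.probabilities.ae.diarrhea_g34",
                  "percent", -10, 10, label = "rare AE"),
    dsa_parameter("arms.palbociclib.probabilities.prog", "percent", -10, 10,
                  label = "progression")
  )
  dsa <- run_dsa(inputs, params, c("ribociclib", "palbociclib"))
  expect_identical(nrow(dsa), 1L)
  expect_identical(dsa$parameter, "progression")
  expect_identical(attr(dsa, "excluded"),
                   "arms.palbociclib.probabilities.ae.diarrhea_g34")
})

test_that("threshold search matches the algebraic cutoff on a linear model", {
  # one-cycle deathless model: total cost of arm B equals its cycle cost x,
  # QALYs are fixed, so the ICER of A over B crosses the WTP at
  # x* = cost_A - wtp * (u_A - u_B) / 12.
  toy <- linear_toy_inputs(cost_a = 1000, cost_b = 800, u_a = 0.9, u_b = 0.6,
                           wtp = 12000)
  x_star <- 1000 - 12000 * (0.9 - 0.6) / 12
  res <- threshold_search(toy, "arms.B.costs.tier0", c("A", "B"),
                          lo = 500, hi = 900)
  expect_equal(res$cutoff, x_star, tolerance = 1e-6)
  expect_identical(sort(c(res$below$preferred, res$above$preferred)),
                   c("A", "B"))
  # verified flip on the two sides of the cutoff
  expect_false(identical(res$below$preferred, res$above$preferred))

  # factor scale finds the same cutoff relative to base
  res_f <- threshold_search(toy, "arms.B.costs.tier0", c("A", "B"),
                            lo = 500 / 800, hi = 900 / 800,
                            scale = "factor")
  expect_equal(res_f$cutoff, x_star, tolerance = 1e-5)

  # a parameter with no effect on the comparison cannot cross
  expect_error(
    threshold_search(toy, "arms.B.utilities.pd", c("A", "B"),
                     lo = 0.1, hi = 0.9),
    "no conclusion flip"
  )
})

test_that("tornado ranks by ICER span, flags dominance, ignores input order", {
  toy <- linear_toy_inputs()
  params <- list(
    dsa_parameter("arms.B.costs.tier0", "percent", -15, 15,
                  label = "B cycle cost"),
    dsa_parameter("arms.B.utilities.pd", "percent", -10, 10,
                  label = "PD utility (unvisited state)"),
    dsa_parameter("arms.A.costs.tier0", "percent", -5, 5,
                  label = "A cycle cost")
  )
  tt <- tornado(toy, params, c("A", "B"))
  expect_identical(tt$parameter[3], "PD utility (unvisited state)")
  expect_identical(tt$span[3], 0)
  expect_true(all(diff(tt$span) <= 0))
  # permutation invariance
  tt2 <- tornado(toy, params[c(3, 1, 2)], c("A", "B"))
  expect_equal(tt, tt2)

  # a bound that reaches dominance is flagged, not given a fake ICER
  params_dom <- list(dsa_parameter("arms.B.costs.tier0", "absolute_bounds",
                                   low = 1100, high = 1200, label = "B cost"))
  td <- tornado(toy, params_dom, c("A", "B"))
  expect_true(is.na(td$icer_low) && is.na(td$icer_high))
  expect_identical(td$flag_low, "dominant")
  expect_identical(td$span, 0)

  p <- plot_tornado(tt)
  expect_s3_class(p, "ggplot")
})

test_that("packaged sensitivity specs load and resolve against the base case", {
  for (f in c("dsa_ribociclib_vs_palbociclib.yaml",
              "dsa_ribociclib_vs_abemaciclib.yaml")) {
    spec <- load_dsa_spec(cdk46_example(f))
    expect_length(spec$comparison, 2)
    expect_gt(length(spec$parameters), 10)
    inputs <- base_inputs()
    for (p in spec$parameters) {
      for (path in cdk46cea:::expand_paths(inputs, p$path)) {
        expect_true(is.numeric(cdk46cea:::resolve_path(inputs, path)))
      }
    }
  }
})
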