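# Synthetic arm/scenario generation: random but always-valid treatment arms
# bracketing the base case's magnitudes, plus degenerate scenarios with
# closed-form expectations used to verify the engine.

#' Specify a synthetic scenario generator
#'
#' Sampling ranges bracket the base-case magnitudes by roughly an order of
#' magnitude either way, stressing numerical behaviour without leaving the
#' plausible cost-effectiveness regime: cycle costs log-uniform on
#' [500, 50000] QAR, utilities uniform on (0.3, 0.95], monthly transition
#' probabilities uniform on [0, 0.1], adverse-event incidences uniform on
#' [0, 0.06].
#'
#' @param seed Integer seed; generation is reproducible given the seed.
#' @param n_arms Number of arms a multi-arm consumer may request.
#' @param cost_range,utility_range,prob_range,ae_range Sampling bounds.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, n_arms = 2L,
                          cost_range = c(500, 50000),
                          utility_range = c(0.3, 0.95),
                          prob_range = c(0, 0.1),
                          ae_range = c(0, 0.06)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed), n_arms = as.integer(n_arms),
                 cost_range = cost_range, utility_range = utility_range,
                 prob_range = prob_range, ae_range = ae_range),
            class = "scenario_spec")
}

with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random, always-valid treatment arm
#'
#' Samples an arm from the spec's ranges and rejects draws that fail
#' [validate_arm()] (per-tier outflow above 1 is impossible within the
#' default ranges but perverse custom ranges are guarded by a rejection
#' cap).  The same `(spec, index)` pair always yields the same arm; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [scenario_spec()].
#' @param index Arm index (distinct indices give independent arms).
#' @param degenerate Optional degeneracy flag: `"immortal"` zeroes both
#'   death probabilities; `"frozen"` zeroes every transition out of the
#'   entry state.
#' @return A [treatment_arm()].
#' @export
gen_random_arm <- function(spec, index = 1L, degenerate = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_preserved_rng(spec$seed + 7919L * as.integer(index), {
    runif_r <- function(rg, n = 1L) stats::runif(n, rg[1L], rg[2L])
    for (attempt in seq_len(1000L)) {
      lcost <- log(spec$cost_range)
      tiers <- sort(exp(runif_r(lcost, 3L)), decreasing = TRUE)
      ae_p <- runif_r(spec$ae_range, 4L)
      arm <- structure(
        list(
          name = sprintf("synthetic_%d", index),
          costs = list(tier0 = tiers[1L], tier1 = tiers[2L],
                       tier2 = tiers[3L], pd = exp(runif_r(lcost))),
          utilities = list(
            pfs = runif_r(spec$utility_range),
            pd = runif_r(spec$utility_range),
            ae = list(neutropenia_g34 = runif_r(spec$utility_range),
                      diarrhea_g34 = runif_r(spec$utility_range),
                      hepatotox_g3 = runif_r(spec$utility_range),
                      hepatotox_g4 = runif_r(spec$utility_range))
          ),
          probabilities = list(
            prog = runif_r(spec$prob_range),
            pfs_death = runif_r(spec$prob_range),
            pd_death = runif_r(spec$prob_range),
            reduce1 = runif_r(spec$prob_range),
            reduce2 = runif_r(spec$prob_range),
            disc = runif_r(spec$prob_range),
            ae = list(neutropenia_g34 = ae_p[1L], diarrhea_g34 = ae_p[2L],
                      hepatotox_g3 = ae_p[3L], hepatotox_g4 = ae_p[4L],
                      qtc_480_500 = 0, qtc_gt_500 = 0)
          )
        ),
        class = "treatment_arm"
      )
      if (!is.null(degenerate)) {
        if (degenerate == "immortal") {
          arm$probabilities$pfs_death <- 0
          arm$probabilities$pd_death <- 0
        } else if (degenerate == "frozen") {
          arm$probabilities[c("prog", "pfs_death", "reduce1", "reduce2",
                              "disc")] <- list(0, 0, 0, 0, 0)
        } else {
          stop("unknown degeneracy flag: ", degenerate, call. = FALSE)
        }
      }
      if (!length(validate_arm(arm, model_settings(disc_routing = "pd")))) {
        return(arm)
      }
    }
    stop("could not sample a valid arm in 1000 attempts; ",
         "the spec's ranges are pathological", call. = FALSE)
  })
}

#' Closed-form verification scenarios
#'
#' Returns a `(arm, settings, expectation)` triple for which the engine's
#' totals have an analytic value:
#'
#' * `immortal_full_health`: no deaths, no progression, utility 1, no
#'   discounting; the expected total over 120 one-month cycles is exactly
#'   10 QALYs.
#' * `two_state_geometric`: a single PFS state emptying into death with
#'   monthly probability `q`, end-of-cycle crediting, no discounting;
#'   expected person-months are the geometric sum
#'   `(1 - q) (1 - (1 - q)^T) / q`.
#' * `single_cycle`: one cycle with half-cycle correction and discounting;
#'   cost and QALY follow from one hand-computed matrix multiply.
#'
#' @param kind One of `"immortal_full_health"`, `"two_state_geometric"`,
#'   `"single_cycle"`.
#' @param q Monthly death probability for the geometric scenario.
#' @return List with `arm`, `settings` and `expected` (named list of
#'   analytic totals).
#' @export
gen_closed_form_scenario <- function(kind = c("immortal_full_health",
                                              "two_state_geometric",
                                              "single_cycle"),
                                     q = 0.05) {
  kind <- match.arg(kind)
  base_ae_u <- list()
  base_ae_p <- list(neutropenia_g34 = 0, diarrhea_g34 = 0, hepatotox_g3 = 0,
                    hepatotox_g4 = 0, qtc_480_500 = 0, qtc_gt_500 = 0)
  mk_arm <- function(name, cost, u_pfs, p) {
    structure(
      list(name = name,
           costs = list(tier0 = cost, pd = cost),
           utilities = list(pfs = u_pfs, pd = u_pfs, ae = base_ae_u),
           probabilities = c(p, list(ae = base_ae_p))),
      class = "treatment_arm"
    )
  }
  switch(kind,
    immortal_full_health = {
      arm <- mk_arm("immortal", 1200, 1,
                    list(prog = 0, pfs_death = 0, pd_death = 0,
                         reduce1 = 0, reduce2 = 0, disc = 0))
      settings <- model_settings(horizon_cycles = 120L,
                                 annual_discount_rate = 0,
                                 wcc_method = "half_cycle")
      list(arm = arm, settings = settings,
           expected = list(total_qaly = 10,
                           total_cost = 1200 * 120))
    },
    two_state_geometric = {
      stopifnot(q > 0, q < 1)
      arm <- mk_arm("geometric", 1000, 1,
                    list(prog = 0, pfs_death = q, pd_death = 0,
                         reduce1 = 0, reduce2 = 0, disc = 0))
      settings <- model_settings(horizon_cycles = 120L,
                                 annual_discount_rate = 0,
                                 wcc_method = "none")
      T_ <- 120
      person_months <- (1 - q) * (1 - (1 - q)^T_) / q
      list(arm = arm, settings = settings,
           expected = list(person_months = person_months,
                           total_cost = 1000 * person_months,
                           total_qaly = person_months / 12))
    },
    single_cycle = {
      arm <- mk_arm("one_cycle", 2000, 0.8,
                    list(prog = 0, pfs_death = 0.3, pd_death = 0,
                         reduce1 = 0, reduce2 = 0, disc = 0))
      settings <- model_settings(horizon_cycles = 1L,
                                 annual_discount_rate = 0.03,
                                 wcc_method = "half_cycle")
      credit <- (1 + 0.7) / 2
      disc <- 1.03^(-1 / 12)
      list(arm = arm, settings = settings,
           expected = list(total_cost = disc * credit * 2000,
                           total_qaly = disc * credit * 0.8 / 12))
    }
  )
}
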