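# Markov cohort engine: one-cycle transition kernel, cohort trace with
# within-cycle correction and discounting, and cost/QALY accumulation.
#
# State space per arm: one progression-free state per dose tier
# (PFS_T0 [, PFS_T1, PFS_T2]), then PD, then DEAD.  DEAD is absorbing and
# the coarse ordering PFS -> PD -> DEAD is unidirectional; dose tiers only
# move downward.

arm_tiers <- function(arm) {
  intersect(c("tier0", "tier1", "tier2"), names(arm$costs))
}

arm_states <- function(arm) {
  tiers <- arm_tiers(arm)
  c(sub("tier", "PFS_T", tiers), "PD", "DEAD")
}

#' Build the one-cycle transition matrix for an arm
#'
#' From each progression-free tier the cohort moves to PD with the
#' progression probability (plus the discontinuation probability when
#' `disc_routing = "pd"`), to DEAD with the PFS death probability, and one
#' tier down with the applicable dose-reduction probability (tier0 to tier1
#' with `reduce1`, tier1 to tier2 with `reduce2`; the lowest tier has no
#' further reduction).  Residual mass stays put.  From PD the cohort moves
#' to DEAD with the PD death probability, else stays.  Rows are never
#' renormalised: if the explicit outflows of any tier exceed 1 an error is
#' raised naming the tier.
#'
#' @param arm A [treatment_arm()].
#' @param settings [model_settings()]; `disc_routing` selects whether
#'   toxicity discontinuation moves occupancy to PD.
#' @return A square row-stochastic matrix with dimnames from the arm's
#'   state space.
#' @examples
#' inputs <- load_inputs(cdk46_example("table1_base_case.yaml"))
#' build_transition_matrix(inputs$arms$letrozole, inputs$settings)
#' @export
build_transition_matrix <- function(arm, settings = model_settings()) {
  states <- arm_states(arm)
  n_tiers <- length(states) - 2L
  ns <- length(states)
  p <- arm$probabilities
  disc <- if (identical(settings$disc_routing, "pd")) p$disc else 0
  P <- matrix(0, ns, ns, dimnames = list(states, states))
  for (j in seq_len(n_tiers)) {
    hop <- if (j == 1L && n_tiers > 1L) p$reduce1
           else if (j == 2L && n_tiers > 2L) p$reduce2
           else 0
    out <- p$prog + disc + p$pfs_death + hop
    if (out > 1 + .tol$invariant) {
      stop(sprintf("arm `%s`: tier %d outflow probability %.6f exceeds 1",
                   arm$name, j - 1L, out), call. = FALSE)
    }
    P[j, ns - 1L] <- p$prog + disc
    P[j, ns] <- p$pfs_death
    if (hop > 0) P[j, j + 1L] <- hop
    P[j, j] <- 1 - out
  }
  P[ns - 1L, ns] <- p$pd_death
  P[ns - 1L, ns - 1L] <- 1 - p$pd_death
  P[ns, ns] <- 1
  P
}

#' Effective per-cycle utility of a state
#'
#' Progression-free utility is a mutually-exclusive mixture of the arm's
#' PFS utility and the absolute utilities of the utility-bearing grade-3/4
#' adverse events, weighted by their monthly incidences:
#' `u_eff = (1 - sum(p_j)) * u_pfs + sum(p_j * u_j)`.  All tiers share one
#' effective utility.  PD returns the PD utility; DEAD returns 0.
#'
#' @param arm A [treatment_arm()].
#' @param state A state id from the arm's state space (e.g. `"PFS_T0"`,
#'   `"PD"`, `"DEAD"`).
#' @return Utility value in `[0, 1]`.
#' @export
effective_cycle_utility <- function(arm, state) {
  if (state == "DEAD") return(0)
  if (state == "PD") return(arm$utilities$pd)
  if (!state %in% arm_states(arm)) {
    stop("unknown state `", state, "` for arm `", arm$name, "`",
         call. = FALSE)
  }
  ae_u <- unlist(arm$utilities$ae)
  p_ae <- vapply(names(ae_u),
                 function(nm) arm$probabilities$ae[[nm]] %||% 0, numeric(1))
  if (sum(p_ae) >= 1) {
    stop("arm `", arm$name,
         "`: utility-bearing AE incidences sum to 1 or more", call. = FALSE)
  }
  (1 - sum(p_ae)) * arm$utilities$pfs + sum(p_ae * ae_u)
}

state_cycle_costs <- function(arm) {
  tiers <- arm_tiers(arm)
  c(unlist(arm$costs[tiers], use.names = FALSE), arm$costs$pd, 0)
}

state_utilities <- function(arm) {
  n_tiers <- length(arm_tiers(arm))
  c(rep(effective_cycle_utility(arm, "PFS_T0"), n_tiers),
    arm$utilities$pd, 0)
}

#' Run the cohort trace for one arm
#'
#' Starts the whole cohort in the full-dose progression-free state and
#' iterates the one-cycle kernel over the model horizon.  Per cycle `k`
#' (1-based), the credited occupancy is the average of the start- and
#' end-of-cycle rows under half-cycle correction (or the end-of-cycle row
#' with `wcc_method = "none"`), the discount factor is
#' `(1 + annual_rate)^(-k / 12)` (end-of-cycle timing), and
#' costs/QALYs are credited as occupancy times per-cycle state cost /
#' state utility over 12.
#'
#' @param arm A [treatment_arm()].
#' @param settings [model_settings()].
#' @return A `cohort_trace`: list with `states`, `occupancy`
#'   (`horizon + 1` rows; row 1 is model entry), `credit` (credited
#'   occupancy per cycle), `discount` (per-cycle factors), `cycle_cost` and
#'   `cycle_qaly` (discounted per-cycle increments), and `settings`.
#' @export
run_trace <- function(arm, settings = model_settings()) {
  P <- build_transition_matrix(arm, settings)
  states <- colnames(P)
  ns <- length(states)
  T_ <- settings$horizon_cycles
  occ <- matrix(0, T_ + 1L, ns, dimnames = list(NULL, states))
  occ[1L, 1L] <- 1
  for (k in seq_len(T_)) occ[k + 1L, ] <- occ[k, ] %*% P

  credit <- switch(settings$wcc_method,
    half_cycle = (occ[-(T_ + 1L), , drop = FALSE] +
                  occ[-1L, , drop = FALSE]) / 2,
    none = occ[-1L, , drop = FALSE]
  )
  disc <- (1 + settings$annual_discount_rate)^
    (-(seq_len(T_) * settings$cycle_length_months) / 12)
  costs <- state_cycle_costs(arm)
  utils <- state_utilities(arm)
  cycle_cost <- disc * as.vector(credit %*% costs)
  cycle_qaly <- disc * as.vector(credit %*% utils) *
    settings$cycle_length_months / 12

  structure(
    list(states = states, occupancy = occ, credit = credit, discount = disc,
         cycle_cost = cycle_cost, cycle_qaly = cycle_qaly,
         settings = settings),
    class = "cohort_trace"
  )
}

#' Accumulate a cohort trace into arm totals
#'
#' Sums the discounted per-cycle increments into total and per-state-group
#' (progression-free aggregate over all tiers, and PD) costs and QALYs.
#'
#' @param trace A `cohort_trace` from [run_trace()].
#' @param arm The [treatment_arm()] the trace was run for.
#' @return An `arm_result`: list with `arm`, `total_cost`, `total_qaly`,
#'   `pfs_cost`, `pd_cost`, `pfs_qaly`, `pd_qaly` and the `trace`.
#' @export
accumulate_trace <- function(trace, arm) {
  states <- trace$states
  pfs_idx <- grep("^PFS_", states)
  pd_idx <- which(states == "PD")
  costs <- state_cycle_costs(arm)
  utils <- state_utilities(arm)
  s <- trace$settings
  part_cost <- function(idx) {
    sum(trace$discount *
          as.vector(trace$credit[, idx, drop = FALSE] %*% costs[idx]))
  }
  part_qaly <- function(idx) {
    sum(trace$discount *
          as.vector(trace$credit[, idx, drop = FALSE] %*% utils[idx])) *
      s$cycle_length_months / 12
  }
  structure(
    list(arm = arm$name,
         total_cost = sum(trace$cycle_cost),
         total_qaly = sum(trace$cycle_qaly),
         pfs_cost = part_cost(pfs_idx), pd_cost = part_cost(pd_idx),
         pfs_qaly = part_qaly(pfs_idx), pd_qaly = part_qaly(pd_idx),
         trace = trace),
    class = "arm_result"
  )
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_trace()] then [accumulate_trace()].
#'
#' @inheritParams run_trace
#' @return An `arm_result`.
#' @export
run_arm <- function(arm, settings = model_settings()) {
  accumulate_trace(run_trace(arm, settings), arm)
}

#' Run every arm of an input set
#'
#' @param inputs A `cea_inputs` object from [load_inputs()].
#' @param settings Optional [model_settings()] overriding the ones carried
#'   by `inputs`.
#' @return Named list of `arm_result` objects.
#' @examples
#' inputs <- load_inputs(cdk46_example("table1_base_case.yaml"))
#' results <- run_model(inputs)
#' results$letrozole$total_cost
#' @export
run_model <- function(inputs, settings = NULL) {
  stopifnot(inherits(inputs, "cea_inputs"))
  settings <- settings %||% inputs$settings
  lapply(inputs$arms, run_arm, settings = settings)
}

#' Construct an arm result from known totals
#'
#' Builds an `arm_result` directly from reported totals (no trace), so that
#' the comparison layer can be exercised on published summary tables.
#'
#' @param arm Arm label.
#' @param total_cost,total_qaly Totals for the arm.
#' @param pfs_cost,pd_cost,pfs_qaly,pd_qaly Optional per-state-group splits.
#' @return An `arm_result` with a `NULL` trace.
#' @export
arm_result <- function(arm, total_cost, total_qaly,
                       pfs_cost = NA_real_, pd_cost = NA_real_,
                       pfs_qaly = NA_real_, pd_qaly = NA_real_) {
  structure(
    list(arm = arm, total_cost = total_cost, total_qaly = total_qaly,
         pfs_cost = pfs_cost, pd_cost = pd_cost,
         pfs_qaly = pfs_qaly, pd_qaly = pd_qaly, trace = NULL),
    class = "arm_result"
  )
}

#' Export a cohort trace as a data frame
#'
#' @param trace A `cohort_trace`.
#' @return A tibble with columns `cycle`, one occupancy column per state,
#'   `cycle_cost`, `cycle_qaly`, `cum_cost`, `cum_qaly`.  Cycle 0 is model
#'   entry (no accrual).
#' @export
trace_table <- function(trace) {
  T_ <- nrow(trace$occupancy) - 1L
  occ <- as.data.frame(trace$occupancy)
  out <- tibble::as_tibble(cbind(
    data.frame(cycle = 0:T_),
    occ,
    data.frame(cycle_cost = c(0, trace$cycle_cost),
               cycle_qaly = c(0, trace$cycle_qaly))
  ))
  out$cum_cost <- cumsum(out$cycle_cost)
  out$cum_qaly <- cumsum(out$cycle_qaly)
  out
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm `%s`: total cost %s, total QALYs %.4f\n", x$arm,
              format(round(x$total_cost), big.mark = ","), x$total_qaly))
  if (!is.na(x$pfs_cost)) {
    cat(sprintf("  PFS: cost %s, QALYs %.4f;  PD: cost %s, QALYs %.4f\n",
                format(round(x$pfs_cost), big.mark = ","), x$pfs_qaly,
                format(round(x$pd_cost), big.mark = ","), x$pd_qaly))
  }
  invisible(x)
}
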