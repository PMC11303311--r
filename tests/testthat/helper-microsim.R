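# Individual-level microsimulation oracle for the cohort engine: simulates
# n independent patients through the arm's one-cycle kernel and accumulates
# each patient's discounted QALYs under the same crediting convention.  The
# cohort trace is the exact expectation of this process, so the engine
# total must sit within Monte-Carlo error of the simulated mean.

microsim_total_qaly <- function(arm, settings, n = 1e5, seed = 1L) {
  P <- build_transition_matrix(arm, settings)
  states <- colnames(P)
  u <- vapply(states, function(s) effective_cycle_utility(arm, s),
              numeric(1))
  Pcum <- t(apply(P, 1L, cumsum))
  T_ <- settings$horizon_cycles
  disc <- (1 + settings$annual_discount_rate)^(-seq_len(T_) / 12)
  half <- identical(settings$wcc_method, "half_cycle")

  set.seed(seed)
  state <- rep(1L, n)
  total <- numeric(n)
  for (k in seq_len(T_)) {
    r <- runif(n)
    nxt <- integer(n)
    for (s in unique(state)) {
      idx <- state == s
      nxt[idx] <- findInterval(r[idx], Pcum[s, ]) + 1L
    }
    credit <- if (half) (u[state] + u[nxt]) / 2 else u[nxt]
    total <- total + disc[k] * credit / 12
    state <- nxt
  }
  list(mean = mean(total), se = stats::sd(total) / sqrt(n), n = n)
}
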