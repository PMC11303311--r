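# Conversions between cumulative probabilities, hazard rates and fixed-time
# probabilities, used to place trial-derived quantities on the model's
# one-month cycle grid.  All functions are pure and vectorised.

# Numerical tolerances shared across the package.
.tol <- list(
  roundtrip = 1e-10,  # prob -> rate -> prob identity
  invariant = 1e-12,  # internal consistency (row sums, rate/prob pairs)
  qaly_eps  = 1e-9,   # effectiveness differences below this count as equal
  cost_eps  = 1e-6    # cost differences below this count as equal (QAR)
)

#' Convert a cumulative probability to a hazard rate
#'
#' Treats `p` as the probability that an event has occurred by time `t`
#' under a constant hazard, and returns that hazard:
#' `r = -log(1 - p) / t`.
#'
#' @param p Probability in `[0, 1)` observed over the interval.
#' @param t Interval length in months (default 1). Must be positive.
#' @return Hazard rate per month, `>= 0`; zero exactly when `p == 0`.
#' @seealso [rate_to_prob()], [rescale_prob()]
#' @examples
#' cumprob_to_rate(0.5)          # log(2)
#' cumprob_to_rate(0.19, t = 12) # monthly hazard from a 12-month probability
#' @export
cumprob_to_rate <- function(p, t = 1) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(t <= 0)) stop("interval `t` must be positive", call. = FALSE)
  if (any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1); p = 1 implies an infinite rate", call. = FALSE)
  }
  -log1p(-p) / t
}

#' Convert a hazard rate to a fixed-time probability
#'
#' Inverse of [cumprob_to_rate()]: `p = 1 - exp(-r * t)`.
#'
#' @param r Hazard rate per month, `>= 0`.
#' @param t Interval length in months (default 1). Must be positive.
#' @return Probability in `[0, 1)`, strictly increasing in both `r` and `t`.
#' @export
rate_to_prob <- function(r, t = 1) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(t <= 0)) stop("interval `t` must be positive", call. = FALSE)
  if (any(r < 0)) stop("rate `r` must be non-negative", call. = FALSE)
  -expm1(-r * t)
}

#' Rescale a probability to a different time interval
#'
#' Composition of [cumprob_to_rate()] and [rate_to_prob()] under a constant
#' hazard, which reduces to `1 - (1 - p)^(t2 / t1)`.
#'
#' @param p Probability in `[0, 1)` observed over `t1` months.
#' @param t1 Source interval in months.
#' @param t2 Target interval in months.
#' @return Probability over `t2` months.
#' @examples
#' rescale_prob(0.19, t1 = 12, t2 = 1) # annual risk to monthly risk
#' @export
rescale_prob <- function(p, t1, t2) {
  rate_to_prob(cumprob_to_rate(p, t1), t2)
}

#' Split a total death probability between causes
#'
#' Divides a monthly all-cause death probability into a background
#' (incidence) component and a progression-attributed component.  Trials
#' behind the model report deaths without attribution, so the split uses a
#' fixed fraction pair, 13% incidence / 87% progression by default.
#'
#' The split is performed on the hazard scale: the total probability is
#' converted to a rate, the fractions partition that rate exactly, and each
#' component rate is converted back to a monthly probability.  The component
#' rates sum exactly to the total rate; the component probabilities sum to
#' at least the input probability (the transform is concave through zero).
#' `split_scale = "probability"` instead applies the fractions to the
#' probability itself (components then sum exactly on the probability scale).
#'
#' @param p_death_total Monthly all-cause death probability in `[0, 1)`.
#' @param f_incidence Fraction of deaths attributed to background incidence.
#' @param f_progression Fraction attributed to disease progression. The two
#'   fractions must be in `[0, 1]` and sum to 1.
#' @param split_scale `"rate"` (default) or `"probability"`.
#' @return Named numeric vector with components `incidence` and
#'   `progression`.
#' @examples
#' split_death_prob(0.01)
#' @export
split_death_prob <- function(p_death_total, f_incidence = 0.13,
                             f_progression = 0.87,
                             split_scale = c("rate", "probability")) {
  split_scale <- match.arg(split_scale)
  stopifnot(length(f_incidence) == 1L, length(f_progression) == 1L)
  if (f_incidence < 0 || f_progression < 0 ||
      abs(f_incidence + f_progression - 1) > .tol$invariant) {
    stop("death-split fractions must be in [0, 1] and sum to 1", call. = FALSE)
  }
  if (split_scale == "rate") {
    r <- cumprob_to_rate(p_death_total, 1)
    c(incidence   = rate_to_prob(f_incidence * r, 1),
      progression = rate_to_prob(f_progression * r, 1))
  } else {
    if (any(p_death_total < 0) || any(p_death_total >= 1)) {
      stop("`p_death_total` must lie in [0, 1)", call. = FALSE)
    }
    c(incidence   = f_incidence * p_death_total,
      progression = f_progression * p_death_total)
  }
}
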