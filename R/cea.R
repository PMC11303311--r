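# Incremental cost-effectiveness analysis: pairwise ICERs, dominance
# classification, willingness-to-pay decisions and the full league table.

#' Compare two arm results
#'
#' Computes incremental cost and effectiveness of `intervention` over
#' `comparator`, classifies dominance, and applies the willingness-to-pay
#' decision rule.
#'
#' Quadrants (eps: effect differences below 1e-9 QALYs and cost differences
#' below 1e-6 QAR count as ties):
#' * cheaper and more effective: `dominant` — the intervention is adopted
#'   outright.
#' * costlier and less effective: `dominated`.
#' * costlier and more effective: ICER = delta cost / delta QALY;
#'   cost-effective iff ICER is at most the WTP.
#' * cheaper and less effective: the ICER is reported from the perspective
#'   of the costlier arm (the comparator): the intervention (a cost-saving
#'   option) is preferred iff that ICER exceeds the WTP, i.e. the QALYs it
#'   forgoes are not worth their price.
#'
#' @param intervention,comparator `arm_result` objects (from [run_arm()] or
#'   [arm_result()]).
#' @param wtp Willingness-to-pay threshold in QAR per QALY.
#' @return A `comparison_result`: list with `intervention`, `comparator`,
#'   `delta_cost`, `delta_qaly`, `icer` (`NA` when undefined), `dominance`
#'   (`"dominant"`, `"dominated"`, `"icer_defined"`, `"equal"`),
#'   `decision_at_wtp` (`"dominant"`, `"dominated"`, `"cost_effective"`,
#'   `"not_cost_effective"`, `"equal"`), `preferred` (arm label preferred at
#'   the WTP) and `wtp`.
#' @examples
#' a <- arm_result("palbociclib", 938439, 4.406)
#' b <- arm_result("letrozole", 100855, 2.093)
#' compare_arms(a, b, wtp = 448785)
#' @export
compare_arms <- function(intervention, comparator, wtp = 448785) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  if (!is.null(intervention$trace) && !is.null(comparator$trace) &&
      !identical(intervention$trace$settings, comparator$trace$settings)) {
    stop("arm results were produced under different model settings",
         call. = FALSE)
  }
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  tie_c <- abs(dc) <= .tol$cost_eps
  tie_e <- abs(de) <= .tol$qaly_eps

  icer <- NA_real_
  if (tie_c && tie_e) {
    dominance <- "equal"; decision <- "equal"
    preferred <- comparator$arm
  } else if (de > .tol$qaly_eps && dc < -.tol$cost_eps ||
             (tie_e && dc < 0) || (tie_c && de > 0)) {
    dominance <- "dominant"; decision <- "dominant"
    preferred <- intervention$arm
  } else if (de < -.tol$qaly_eps && dc > .tol$cost_eps ||
             (tie_e && dc > 0) || (tie_c && de < 0)) {
    dominance <- "dominated"; decision <- "dominated"
    preferred <- comparator$arm
  } else {
    dominance <- "icer_defined"
    icer <- dc / de
    if (de > 0) {
      decision <- if (icer <= wtp) "cost_effective" else "not_cost_effective"
      preferred <- if (icer <= wtp) intervention$arm else comparator$arm
    } else {
      # intervention cheaper and less effective: ICER is the comparator's
      # cost per QALY gained; the saving wins iff that exceeds the WTP.
      decision <- if (icer > wtp) "cost_effective" else "not_cost_effective"
      preferred <- if (icer > wtp) intervention$arm else comparator$arm
    }
  }
  structure(
    list(intervention = intervention$arm, comparator = comparator$arm,
         delta_cost = dc, delta_qaly = de, icer = icer,
         dominance = dominance, decision_at_wtp = decision,
         preferred = preferred, wtp = wtp),
    class = "comparison_result"
  )
}

#' Full pairwise league table
#'
#' Emits one row per arm (totals and per-state-group splits) plus every
#' comparison of a non-reference arm against the reference and all pairwise
#' comparisons among the non-reference arms.
#'
#' @param results Named list of `arm_result` objects (at least two).
#' @param wtp Willingness-to-pay threshold in QAR per QALY.
#' @param reference Name of the reference arm (default `"letrozole"` when
#'   present, else the first arm).
#' @return A list with `arms` (tibble of per-arm totals, reported at whole
#'   QAR / 4-decimal QALYs) and `comparisons` (tibble with incremental
#'   cost, incremental QALYs, ICER, dominance and decision per ordered
#'   pair).
#' @export
league_table <- function(results, wtp = 448785, reference = NULL) {
  if (length(results) < 2L) {
    stop("league_table needs at least two arm results", call. = FALSE)
  }
  nms <- vapply(results, `[[`, character(1), "arm")
  names(results) <- nms
  reference <- reference %||%
    (if ("letrozole" %in% nms) "letrozole" else nms[[1L]])
  if (!reference %in% nms) stop("unknown reference arm: ", reference,
                                call. = FALSE)

  arms <- tibble::tibble(
    arm = nms,
    total_cost = round(vapply(results, `[[`, numeric(1), "total_cost")),
    pfs_cost = round(vapply(results, `[[`, numeric(1), "pfs_cost")),
    pd_cost = round(vapply(results, `[[`, numeric(1), "pd_cost")),
    total_qaly = round(vapply(results, `[[`, numeric(1), "total_qaly"), 4),
    pfs_qaly = round(vapply(results, `[[`, numeric(1), "pfs_qaly"), 4),
    pd_qaly = round(vapply(results, `[[`, numeric(1), "pd_qaly"), 4)
  )

  # Non-reference arms are each compared against the reference; among
  # themselves, each unordered pair is reported once, from the perspective
  # of the more effective arm (the published layout).
  others <- setdiff(nms, reference)
  pairs <- c(
    lapply(others, function(a) c(a, reference)),
    if (length(others) > 1L) {
      lapply(utils::combn(others, 2L, simplify = FALSE), function(p) {
        if (results[[p[1L]]]$total_qaly >= results[[p[2L]]]$total_qaly) {
          p
        } else {
          rev(p)
        }
      })
    }
  )
  rows <- lapply(pairs, function(p) {
    cr <- compare_arms(results[[p[1L]]], results[[p[2L]]], wtp)
    tibble::tibble(
      intervention = cr$intervention, comparator = cr$comparator,
      delta_cost = round(cr$delta_cost),
      delta_qaly = round(cr$delta_qaly, 4),
      icer = if (is.na(cr$icer)) NA_real_ else round(cr$icer),
      dominance = cr$dominance, decision = cr$decision_at_wtp,
      preferred = cr$preferred
    )
  })
  list(arms = arms, comparisons = do.call(rbind, rows),
       reference = reference, wtp = wtp)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: Δcost %s, ΔQALY %.4f\n",
              x$intervention, x$comparator,
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (!is.na(x$icer)) {
    cat(sprintf("  ICER %s per QALY (WTP %s): %s\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ","), x$decision_at_wtp))
  } else {
    cat(sprintf("  %s (no ICER defined)\n", x$dominance))
  }
  cat("  preferred at WTP:", x$preferred, "\n")
  invisible(x)
}
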