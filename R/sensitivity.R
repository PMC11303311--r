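# One-way deterministic sensitivity analysis over costs, utilities and
# transition probabilities; conclusion-flip threshold search by bisection;
# tornado-diagram data.
#
# Parameters are addressed by dot-paths into the input structure, e.g.
# `arms.ribociclib.costs.tier0` or `settings.wtp`.  A `*` arm segment
# (`arms.*.utilities.pd`) fans out over every arm, which is how shared
# inputs such as the PD utility are perturbed consistently.

resolve_path <- function(inputs, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- inputs
  for (s in segs) {
    if (is.null(node[[s]])) {
      stop("cannot resolve path `", path, "` (segment `", s, "`)",
           call. = FALSE)
    }
    node <- node[[s]]
  }
  if (!is.numeric(node) || length(node) != 1L) {
    stop("path `", path, "` does not point at a single numeric value",
         call. = FALSE)
  }
  node
}

assign_path <- function(inputs, path, value) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1L]]
  expr <- Reduce(function(acc, s) call("[[", acc, s), segs,
                 init = quote(inputs))
  eval(call("<-", expr, value))
  inputs
}

expand_paths <- function(inputs, path) {
  if (!grepl(".*.", path, fixed = TRUE)) return(path)
  vapply(names(inputs$arms),
         function(a) sub("*", a, path, fixed = TRUE), character(1))
}

#' Perturb one model input
#'
#' Returns a deep copy of `inputs` with the value at `path` scaled by
#' `factor` or replaced by `value`; the original object is untouched.
#' Perturbed probabilities falling outside `[0, 1]` are clipped to the
#' boundary, never silently: a warning diagnostic is raised.
#'
#' @param inputs A `cea_inputs` object.
#' @param path Dot-path to a single numeric input (an `arms.*.` arm segment
#'   fans out over all arms).
#' @param factor Multiplicative perturbation (e.g. `1.15` for +15%).
#' @param value Replacement value (alternative to `factor`).
#' @return The perturbed `cea_inputs`.
#' @examples
#' inputs <- load_inputs(cdk46_example("table1_base_case.yaml"))
#' up <- perturb_inputs(inputs, "arms.ribociclib.costs.tier0", factor = 1.15)
#' up$arms$ribociclib$costs$tier0
#' @export
perturb_inputs <- function(inputs, path, factor = NULL, value = NULL) {
  stopifnot(inherits(inputs, "cea_inputs"))
  if (is.null(factor) == is.null(value)) {
    stop("supply exactly one of `factor` or `value`", call. = FALSE)
  }
  for (p in expand_paths(inputs, path)) {
    base <- resolve_path(inputs, p)
    new <- if (!is.null(factor)) base * factor else value
    if (grepl("probabilities", p, fixed = TRUE) && (new < 0 || new > 1)) {
      clipped <- min(max(new, 0), 1)
      warning(sprintf("perturbed probability at `%s` (%.6f) clipped to %g",
                      p, new, clipped), call. = FALSE)
      new <- clipped
    }
    inputs <- assign_path(inputs, p, new)
  }
  inputs
}

#' Define a sensitivity parameter
#'
#' @param path Dot-path of the input to vary (see [perturb_inputs()]).
#' @param mode `"percent"`: `low`/`high` are percent changes relative to the
#'   base value (e.g. -15, 15). `"absolute_bounds"`: `low`/`high` are the
#'   bound values themselves (used for published confidence intervals).
#' @param low,high Bounds, `low < high`.
#' @param label Human-readable label for tables and plots.
#' @return A `dsa_parameter` list.
#' @export
dsa_parameter <- function(path, mode = c("percent", "absolute_bounds"),
                          low, high, label = path) {
  mode <- match.arg(mode)
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("need numeric bounds with low < high", call. = FALSE)
  }
  structure(list(path = path, mode = mode, low = low, high = high,
                 label = label),
            class = "dsa_parameter")
}

bound_inputs <- function(inputs, param, bound) {
  b <- param[[bound]]
  if (param$mode == "percent") {
    perturb_inputs(inputs, param$path, factor = 1 + b / 100)
  } else {
    perturb_inputs(inputs, param$path, value = b)
  }
}

run_comparison <- function(inputs, comparison, settings = NULL) {
  settings <- settings %||% inputs$settings
  ri <- run_arm(inputs$arms[[comparison[1L]]], settings)
  rc <- run_arm(inputs$arms[[comparison[2L]]], settings)
  compare_arms(ri, rc, settings$wtp)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the model with each parameter moved to its lower and upper bound
#' (everything else at base) and compares the decision for the comparison
#' under study against the base case.  A parameter is `robust` when the
#' preferred strategy at the willingness-to-pay threshold is unchanged at
#' both bounds, `sensitive` otherwise; the narrative label records any
#' change of decision class that leaves the preferred strategy intact
#' (e.g. a comparison sliding from dominance to a beyond-threshold ICER).
#'
#' Transition/adverse-event probability parameters whose base value is
#' below 0.01 are excluded from the analysis (rare events contribute noise,
#' not signal, at the published reporting precision); exclusions are listed
#' in the `excluded` attribute of the result.
#'
#' @param inputs A `cea_inputs` object (base case).
#' @param params List of [dsa_parameter()] objects.
#' @param comparison Character vector `c(intervention, comparator)`.
#' @param settings Optional [model_settings()] override.
#' @return A tibble with one row per parameter: arm totals, ICER, decision
#'   and preferred strategy at each bound, plus `conclusion`
#'   (`robust`/`sensitive`) and `narrative`.  The base-case
#'   `comparison_result` is attached as attribute `base`.
#' @export
run_dsa <- function(inputs, params, comparison, settings = NULL) {
  stopifnot(length(comparison) == 2L,
            all(comparison %in% names(inputs$arms)))
  settings <- settings %||% inputs$settings
  base <- run_comparison(inputs, comparison, settings)

  is_prob <- vapply(params, function(p)
    grepl("probabilities", p$path, fixed = TRUE), logical(1))
  base_vals <- vapply(params, function(p)
    resolve_path(inputs, expand_paths(inputs, p$path)[[1L]]), numeric(1))
  keep <- !is_prob | base_vals >= 0.01
  excluded <- vapply(params[!keep], `[[`, character(1), "path")
  params <- params[keep]

  rows <- lapply(params, function(pm) {
    res <- lapply(c("low", "high"), function(b) {
      run_comparison(bound_inputs(inputs, pm, b), comparison, settings)
    })
    names(res) <- c("low", "high")
    same_class <- vapply(res, function(r)
      identical(r$decision_at_wtp, base$decision_at_wtp), logical(1))
    same_pref <- vapply(res, function(r)
      identical(r$preferred, base$preferred), logical(1))
    conclusion <- if (all(same_pref)) "robust" else "sensitive"
    narrative <- if (all(same_pref) && !all(same_class)) {
      sprintf("robust (decision class shifts to %s without changing the preferred strategy)",
              paste(unique(unlist(lapply(res[!same_class], `[[`,
                                         "decision_at_wtp"))),
                    collapse = "/"))
    } else if (!all(same_pref)) {
      sprintf("sensitive (%s preferred at %s bound)",
              paste(unique(vapply(res[!same_pref], `[[`, character(1),
                                  "preferred")), collapse = "/"),
              paste(c("low", "high")[!same_pref], collapse = " and "))
    } else "robust"
    tibble::tibble(
      parameter = pm$label, path = pm$path, mode = pm$mode,
      low = pm$low, high = pm$high,
      delta_cost_low = res$low$delta_cost,
      delta_qaly_low = res$low$delta_qaly,
      icer_low = res$low$icer, decision_low = res$low$decision_at_wtp,
      delta_cost_high = res$high$delta_cost,
      delta_qaly_high = res$high$delta_qaly,
      icer_high = res$high$icer, decision_high = res$high$decision_at_wtp,
      conclusion = conclusion, narrative = narrative
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  attr(out, "excluded") <- excluded
  out
}

#' Conclusion-flip threshold search
#'
#' Finds, by bisection, the value of one input at which the preferred
#' strategy of a comparison flips.  The decision class must differ between
#' the two bracket ends; the returned cutoff is verified by evaluating the
#' model just below and just above it.
#'
#' @param inputs A `cea_inputs` object.
#' @param path Dot-path of the input to vary.
#' @param comparison Character vector `c(intervention, comparator)`.
#' @param lo,hi Bracket for the input's value (absolute values, or factors
#'   when `scale = "factor"`).
#' @param scale `"value"` (default): `lo`/`hi` are input values;
#'   `"factor"`: multiples of the base value.
#' @param tol Relative bisection tolerance (default 1e-6).
#' @param settings Optional [model_settings()] override.
#' @return A `threshold_result`: list with `path`, `cutoff` (input value),
#'   `cutoff_factor` (relative to base), `direction` (preferred strategy
#'   below -> above), `icer_at_cutoff`, and the verification comparisons
#'   `below`/`above`.
#' @export
threshold_search <- function(inputs, path, comparison, lo, hi,
                             scale = c("value", "factor"), tol = 1e-6,
                             settings = NULL) {
  scale <- match.arg(scale)
  settings <- settings %||% inputs$settings
  base_val <- resolve_path(inputs, expand_paths(inputs, path)[[1L]])
  at <- function(x) {
    v <- if (scale == "factor") base_val * x else x
    run_comparison(perturb_inputs(inputs, path, value = v),
                   comparison, settings)
  }
  pref_lo <- at(lo)$preferred
  pref_hi <- at(hi)$preferred
  if (identical(pref_lo, pref_hi)) {
    stop("no conclusion flip inside [", lo, ", ", hi, "] for `", path,
         "` (preferred strategy is `", pref_lo, "` at both ends)",
         call. = FALSE)
  }
  a <- lo; b <- hi
  for (i in seq_len(200L)) {
    mid <- (a + b) / 2
    if (identical(at(mid)$preferred, pref_lo)) a <- mid else b <- mid
    if ((b - a) <= tol * max(abs(a), abs(b), 1)) break
  }
  cutoff <- (a + b) / 2
  eps <- tol * max(abs(cutoff), 1) * 2
  below <- at(cutoff - eps)
  above <- at(cutoff + eps)
  cut_val <- if (scale == "factor") base_val * cutoff else cutoff
  structure(
    list(path = path, cutoff = cut_val,
         cutoff_factor = cut_val / base_val,
         direction = sprintf("%s -> %s", below$preferred, above$preferred),
         icer_at_cutoff = at(cutoff)$icer,
         below = below, above = above, bracket = c(lo, hi), scale = scale),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold on `%s`: cutoff %.4f (%.2f%% of base)\n",
              x$path, x$cutoff, 100 * x$cutoff_factor))
  cat(sprintf("  preferred strategy flips %s\n", x$direction))
  if (!is.na(x$icer_at_cutoff)) {
    cat(sprintf("  ICER at cutoff: %s\n",
                format(round(x$icer_at_cutoff), big.mark = ",")))
  }
  invisible(x)
}

#' Tornado-diagram table
#'
#' Evaluates the comparison's ICER at both bounds of every parameter and
#' ranks parameters by the span of the ICER across their bounds.  When a
#' bound makes the comparison dominant or dominated the ICER is undefined
#' there; the bound is flagged in `flag_low`/`flag_high` (never encoded as
#' an artificial ICER) and such parameters sort by the span convention
#' below.
#'
#' Span convention: both ICERs defined — absolute difference; exactly one
#' defined — infinite (a dominance transition across the range is maximal
#' impact); neither defined — zero (the metric never leaves the dominance
#' regime).  Ties (including the all-flagged case) are broken by parameter
#' label, so the ordering is invariant under permutation of the input list.
#'
#' @inheritParams run_dsa
#' @return A tibble sorted by descending span with columns `parameter`,
#'   `path`, `icer_low`, `icer_high`, `flag_low`, `flag_high`, `span`.
#' @export
tornado <- function(inputs, params, comparison, settings = NULL) {
  if (!length(params)) stop("tornado needs at least one parameter",
                            call. = FALSE)
  dsa <- run_dsa(inputs, params, comparison, settings)
  flag <- function(icer, decision) {
    ifelse(is.na(icer), decision, NA_character_)
  }
  span <- mapply(function(lo, hi) {
    if (!is.na(lo) && !is.na(hi)) abs(hi - lo)
    else if (is.na(lo) && is.na(hi)) 0
    else Inf
  }, dsa$icer_low, dsa$icer_high)
  out <- tibble::tibble(
    parameter = dsa$parameter, path = dsa$path,
    icer_low = dsa$icer_low, icer_high = dsa$icer_high,
    flag_low = flag(dsa$icer_low, dsa$decision_low),
    flag_high = flag(dsa$icer_high, dsa$decision_high),
    span = span
  )
  out[order(-out$span, out$parameter), ]
}

#' Plot a tornado diagram
#'
#' @param tornado_tbl Output of [tornado()].
#' @param base_icer Optional base-case ICER drawn as a reference line.
#' @return A ggplot object: one horizontal bar per parameter spanning
#'   `icer_low`..`icer_high`; bounds flagged as dominant/dominated are
#'   annotated instead of drawn.
#' @export
plot_tornado <- function(tornado_tbl, base_icer = NULL) {
  tt <- tornado_tbl[!is.na(tornado_tbl$icer_low) &
                      !is.na(tornado_tbl$icer_high), ]
  tt$parameter <- factor(tt$parameter, levels = rev(tt$parameter))
  p <- ggplot2::ggplot(tt, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::labs(x = "ICER (QAR per QALY)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(base_icer) && !is.na(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  flagged <- tornado_tbl[is.na(tornado_tbl$icer_low) |
                           is.na(tornado_tbl$icer_high), ]
  if (nrow(flagged)) {
    p <- p + ggplot2::labs(
      caption = sprintf("flagged (dominance at a bound): %s",
                        paste(flagged$parameter, collapse = "; "))
    )
  }
  p
}

#' Load a sensitivity-analysis specification file
#'
#' Reads a YAML/JSON file with keys `comparison` (`intervention`,
#' `comparator`) and `parameters` (each with `path`, `mode`, `low`, `high`,
#' optional `label`).  Packaged specifications mirroring the published
#' one-way analyses ship as `dsa_ribociclib_vs_palbociclib.yaml` and
#' `dsa_ribociclib_vs_abemaciclib.yaml`.
#'
#' @param path Path to the specification file.
#' @return List with `comparison` (character vector of length 2) and
#'   `parameters` (list of [dsa_parameter()]).
#' @export
load_dsa_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$parameters) || !length(raw$parameters)) {
    stop("sensitivity spec has no parameters: ", path, call. = FALSE)
  }
  params <- lapply(raw$parameters, function(p) {
    dsa_parameter(p$path, p$mode %||% "percent", p$low, p$high,
                  p$label %||% p$path)
  })
  list(comparison = c(raw$comparison$intervention, raw$comparison$comparator),
       parameters = params)
}
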