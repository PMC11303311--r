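# Input schema: loading, validation and (re)serialisation of the model's
# treatment-arm inputs and run settings.
#
# The packaged base-case fixture (inst/extdata/table1_base_case.yaml) carries
# the published per-cycle costs (QAR), utilities and monthly transition
# probabilities for the four arms exactly as printed in the source cost study.

.ae_names <- c("neutropenia_g34", "diarrhea_g34", "hepatotox_g3",
               "hepatotox_g4", "qtc_480_500", "qtc_gt_500")

.prob_fields <- c("prog", "pfs_death", "pd_death", "reduce1", "reduce2", "disc")

#' Model run settings
#'
#' @param horizon_cycles Number of model cycles (default 120: ten years of
#'   one-month cycles).
#' @param cycle_length_months Cycle length in months (the model is built on
#'   one-month cycles; other values only rescale reporting of time).
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   effects; must lie in `[0, 0.2]`. Default 0.03.
#' @param wcc_method Within-cycle correction: `"half_cycle"` (default)
#'   credits the average of start- and end-of-cycle occupancy each cycle;
#'   `"none"` credits end-of-cycle occupancy only.
#' @param wtp Willingness-to-pay threshold in QAR per QALY
#'   (default 448785, 1.5 times GDP per capita).
#' @param currency Currency label used in reports.
#' @param disc_routing Where toxicity-driven treatment discontinuation sends
#'   patients: `"stay"` (default) keeps them in their progression-free tier
#'   (discontinuation does not move state occupancy), `"pd"` routes them to
#'   the progressed-disease state (next-line costs and utility). See the
#'   methods vignette for why `"stay"` is the base-case convention.
#' @return A `model_settings` object.
#' @export
model_settings <- function(horizon_cycles = 120L,
                           cycle_length_months = 1,
                           annual_discount_rate = 0.03,
                           wcc_method = c("half_cycle", "none"),
                           wtp = 448785,
                           currency = "QAR",
                           disc_routing = c("stay", "pd")) {
  wcc_method <- match.arg(wcc_method)
  disc_routing <- match.arg(disc_routing)
  horizon_cycles <- as.integer(horizon_cycles)
  if (is.na(horizon_cycles) || horizon_cycles < 1L) {
    stop("`horizon_cycles` must be a positive integer", call. = FALSE)
  }
  if (cycle_length_months <= 0) {
    stop("`cycle_length_months` must be positive", call. = FALSE)
  }
  if (annual_discount_rate < 0 || annual_discount_rate > 0.2) {
    stop("`annual_discount_rate` must lie in [0, 0.2]", call. = FALSE)
  }
  wtp <- as.numeric(wtp)
  if (wtp <= 0) stop("`wtp` must be positive", call. = FALSE)
  structure(
    list(horizon_cycles = horizon_cycles,
         cycle_length_months = cycle_length_months,
         annual_discount_rate = annual_discount_rate,
         wcc_method = wcc_method,
         wtp = wtp,
         currency = currency,
         disc_routing = disc_routing),
    class = "model_settings"
  )
}

#' Construct a treatment arm
#'
#' A treatment arm bundles everything the engine needs for one strategy:
#' per-cycle costs for each dose tier and for progressed disease, state and
#' adverse-event utilities, and the monthly transition probabilities.
#'
#' @param name Arm label (e.g. `"ribociclib"`).
#' @param costs Named list: `tier0` (full dose) and optionally `tier1`,
#'   `tier2` (first/second dose reduction) per-cycle costs, plus `pd`, all in
#'   QAR per one-month cycle. Single-tier arms (letrozole monotherapy) supply
#'   `tier0` only.
#' @param utilities Named list with `pfs`, `pd` in `(0, 1]`, and `ae`, a
#'   named list of absolute health-state utilities for the utility-bearing
#'   adverse events (QTc prolongation events carry no utility and are
#'   omitted here).
#' @param probabilities Named list of monthly probabilities: `prog`
#'   (PFS to PD), `pfs_death`, `pd_death`, `reduce1` (one-level dose
#'   reduction, tier0 to tier1), `reduce2` (tier1 to tier2), `disc`
#'   (toxicity-driven discontinuation), and `ae`, a named list of monthly
#'   adverse-event incidences.
#' @return A validated `treatment_arm` object.
#' @export
treatment_arm <- function(name, costs, utilities, probabilities) {
  arm <- structure(
    list(name = name, costs = costs, utilities = utilities,
         probabilities = probabilities),
    class = "treatment_arm"
  )
  diag <- validate_arm(arm)
  if (length(diag)) {
    stop("invalid treatment arm `", name, "`:\n  ",
         paste(vapply(diag, format_diagnostic, character(1)),
               collapse = "\n  "),
         call. = FALSE)
  }
  arm
}

diagnostic <- function(field, rule, value) {
  list(field = field, rule = rule, value = value)
}

format_diagnostic <- function(d) {
  sprintf("%s: %s (value %s)", d$field, d$rule,
          paste(format(d$value), collapse = ", "))
}

#' Validate a treatment arm
#'
#' Checks the structural invariants of an arm and returns a list of
#' diagnostics (empty when the arm is valid).  Nothing is thrown: callers
#' that require validity should inspect the result (as [treatment_arm()]
#' does).
#'
#' Checks: tier structure (`tier0` always; `tier1`/`tier2` jointly present
#' or jointly absent), positive costs, utilities in `(0, 1]`, probabilities
#' in `[0, 1]`, per-tier total outflow at most 1 under the settings' routing
#' convention, and the summed incidence of utility-bearing adverse events
#' below 1.
#'
#' @param arm A `treatment_arm` (or an equivalently shaped list).
#' @param settings Optional [model_settings()]; the outflow check uses its
#'   `disc_routing` (default settings otherwise).
#' @return A list of diagnostics, each with fields `field`, `rule`, `value`.
#' @export
validate_arm <- function(arm, settings = model_settings()) {
  out <- list()
  note <- function(field, rule, value) {
    out[[length(out) + 1L]] <<- diagnostic(field, rule, value)
  }

  tiers <- intersect(c("tier0", "tier1", "tier2"), names(arm$costs))
  if (!"tier0" %in% tiers) note("costs.tier0", "tier0 cost is required", NA)
  if (xor("tier1" %in% tiers, "tier2" %in% tiers)) {
    note("costs", "tiers 1 and 2 must be jointly present or absent", tiers)
  }
  if (!"pd" %in% names(arm$costs)) note("costs.pd", "pd cost is required", NA)
  for (f in c(tiers, "pd")) {
    v <- arm$costs[[f]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      note(paste0("costs.", f), "cycle cost must be positive", v)
    }
  }

  for (f in c("pfs", "pd")) {
    v <- arm$utilities[[f]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v > 1) {
      note(paste0("utilities.", f), "utility must lie in (0, 1]", v)
    }
  }
  for (f in names(arm$utilities$ae)) {
    v <- arm$utilities$ae[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      note(paste0("utilities.ae.", f), "utility must lie in (0, 1]", v)
    }
  }

  for (f in .prob_fields) {
    v <- arm$probabilities[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      note(paste0("probabilities.", f), "probability must lie in [0, 1]", v)
    }
  }
  for (f in names(arm$probabilities$ae)) {
    v <- arm$probabilities$ae[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      note(paste0("probabilities.ae.", f), "probability must lie in [0, 1]", v)
    }
  }

  # Mixture feasibility: utility-bearing AE incidences must leave room for
  # the AE-free fraction.
  ae_u <- names(arm$utilities$ae)
  p_ae <- unlist(arm$probabilities$ae[ae_u])
  if (length(p_ae) && all(is.finite(p_ae)) && sum(p_ae) >= 1) {
    note("probabilities.ae", "utility-bearing AE incidences must sum below 1",
         sum(p_ae))
  }

  # Per-tier outflow feasibility after tier mapping.
  p <- arm$probabilities
  if (!length(out)) {
    n_tiers <- length(tiers)
    disc <- if (identical(settings$disc_routing, "pd")) p$disc else 0
    for (j in seq_len(n_tiers)) {
      hop <- if (j == 1L && n_tiers > 1L) p$reduce1
             else if (j == 2L && n_tiers > 2L) p$reduce2
             else 0
      outflow <- p$prog + p$pfs_death + disc + hop
      if (outflow > 1) {
        note(sprintf("probabilities (tier %d)", j - 1L),
             "total outflow probability exceeds 1", outflow)
      }
    }
  }
  out
}

#' Load model inputs from a configuration file
#'
#' Reads a YAML (or JSON) configuration with top-level keys `settings` and
#' `arms`, validates every arm, and returns the assembled input set.  The
#' packaged base case is available via
#' `cdk46_example("table1_base_case.yaml")`.
#'
#' @param path Path to the configuration file.
#' @return A `cea_inputs` object: list with `settings` ([model_settings()]),
#'   `arms` (named list of [treatment_arm()]), `reference` (name of the
#'   reference arm) and `schema_version`.
#' @examples
#' inputs <- load_inputs(cdk46_example("table1_base_case.yaml"))
#' names(inputs$arms)
#' @export
load_inputs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$settings) || is.null(raw$arms)) {
    stop("config must have top-level keys `settings` and `arms`",
         call. = FALSE)
  }
  s <- raw$settings
  settings <- model_settings(
    horizon_cycles = s$horizon_cycles %||% 120L,
    cycle_length_months = s$cycle_length_months %||% 1,
    annual_discount_rate = s$annual_discount_rate %||% 0.03,
    wcc_method = s$wcc_method %||% "half_cycle",
    wtp = s$wtp %||% 448785,
    currency = s$currency %||% "QAR",
    disc_routing = s$disc_routing %||% "stay"
  )
  arms <- list()
  reference <- NULL
  for (a in raw$arms) {
    if (is.null(a$name)) stop("every arm needs a `name`", call. = FALSE)
    arm <- structure(
      list(name = a$name, costs = a$costs, utilities = a$utilities,
           probabilities = a$probabilities),
      class = "treatment_arm"
    )
    diag <- validate_arm(arm, settings)
    if (length(diag)) {
      stop("invalid arm `", a$name, "` in ", path, ":\n  ",
           paste(vapply(diag, format_diagnostic, character(1)),
                 collapse = "\n  "),
           call. = FALSE)
    }
    arms[[a$name]] <- arm
    if (isTRUE(a$reference)) reference <- a$name
  }
  structure(
    list(settings = settings, arms = arms,
         reference = reference %||% names(arms)[[1L]],
         schema_version = raw$schema_version %||% 1L),
    class = "cea_inputs"
  )
}

#' Serialise model inputs back to a configuration file
#'
#' Writes a `cea_inputs` object in the same schema accepted by
#' [load_inputs()], so that loading, writing and re-loading round-trips all
#' values.
#'
#' @param inputs A `cea_inputs` object.
#' @param path Output path; format chosen by extension (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_inputs <- function(inputs, path) {
  stopifnot(inherits(inputs, "cea_inputs"))
  arms <- lapply(inputs$arms, function(a) {
    list(name = a$name,
         reference = identical(a$name, inputs$reference),
         costs = a$costs, utilities = a$utilities,
         probabilities = a$probabilities)
  })
  names(arms) <- NULL
  out <- list(schema_version = inputs$schema_version,
              settings = unclass(inputs$settings),
              arms = arms)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 15L)
  }
  invisible(path)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
cdk46_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "cdk46cea")
  if (is.null(file)) list.files(dir) else {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("no packaged file called ", file, call. = FALSE)
    path
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_settings <- function(x, ...) {
  cat("Model settings:\n")
  cat(sprintf("  horizon: %d cycles of %g month(s)\n",
              x$horizon_cycles, x$cycle_length_months))
  cat(sprintf("  discount: %.1f%% annual; within-cycle correction: %s\n",
              100 * x$annual_discount_rate, x$wcc_method))
  cat(sprintf("  WTP: %s %s/QALY; discontinuation routing: %s\n",
              format(x$wtp, big.mark = ","), x$currency, x$disc_routing))
  invisible(x)
}

#' @export
print.treatment_arm <- function(x, ...) {
  tiers <- intersect(c("tier0", "tier1", "tier2"), names(x$costs))
  cat(sprintf("Treatment arm `%s` (%d dose tier%s)\n", x$name,
              length(tiers), if (length(tiers) > 1) "s" else ""))
  cat("  cycle costs:",
      paste(sprintf("%s=%s", c(tiers, "pd"),
                    format(unlist(x$costs[c(tiers, "pd")]), big.mark = ",")),
            collapse = "  "), "\n")
  cat(sprintf("  utilities: pfs=%g pd=%g\n", x$utilities$pfs, x$utilities$pd))
  p <- x$probabilities
  cat(sprintf("  monthly probs: prog=%g pfs_death=%g pd_death=%g disc=%g\n",
              p$prog, p$pfs_death, p$pd_death, p$disc))
  invisible(x)
}

#' @export
print.cea_inputs <- function(x, ...) {
  cat(sprintf("CEA input set: %d arms (reference: %s)\n",
              length(x$arms), x$reference))
  print(x$settings)
  invisible(x)
}
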