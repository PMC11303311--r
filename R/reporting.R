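# Report writers tying the analysis stages into the study workflow
# (base case -> league table -> sensitivity -> tornado), plus the run
# manifest.  A thin command-line wrapper over these functions ships at
# inst/cli/cdk46cea.R.

write_manifest <- function(out_dir, config, settings, files, seed = NULL) {
  manifest <- list(
    tool = "cdk46cea",
    version = as.character(utils::packageVersion("cdk46cea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = normalizePath(config, mustWork = FALSE),
    settings = unclass(settings),
    seed = seed,
    outputs = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) {
    stop("manifest names outputs that were not written: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(path)
}

write_csv0 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  basename(path)
}

#' Run the base case and write the league-table report
#'
#' Loads a configuration, runs every arm, and writes `arm_results.csv`
#' (per-arm totals in the published table layout), `comparisons.csv` (every
#' pairwise comparison with ICER/dominance/decision), one
#' `trace_<arm>.csv` per arm, and `manifest.json`.
#'
#' @param config Path to an input configuration (see [load_inputs()]).
#' @param out_dir Output directory (created if needed).
#' @param horizon_cycles,annual_discount_rate,wcc_method,wtp,disc_routing
#'   Optional overrides of the configuration's settings.
#' @param verbose Echo the resolved conventions.
#' @return Invisibly, a list with `results`, `league` and `files`.
#' @export
write_run_report <- function(config, out_dir,
                             horizon_cycles = NULL,
                             annual_discount_rate = NULL,
                             wcc_method = NULL, wtp = NULL,
                             disc_routing = NULL, verbose = FALSE) {
  inputs <- load_inputs(config)
  s <- inputs$settings
  settings <- model_settings(
    horizon_cycles = horizon_cycles %||% s$horizon_cycles,
    cycle_length_months = s$cycle_length_months,
    annual_discount_rate = annual_discount_rate %||% s$annual_discount_rate,
    wcc_method = wcc_method %||% s$wcc_method,
    wtp = wtp %||% s$wtp,
    currency = s$currency,
    disc_routing = disc_routing %||% s$disc_routing
  )
  if (verbose) print(settings)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- run_model(inputs, settings)
  league <- league_table(results, wtp = settings$wtp,
                         reference = inputs$reference)
  files <- c(
    write_csv0(league$arms, file.path(out_dir, "arm_results.csv")),
    write_csv0(league$comparisons, file.path(out_dir, "comparisons.csv")),
    vapply(names(results), function(a) {
      write_csv0(trace_table(results[[a]]$trace),
                 file.path(out_dir, sprintf("trace_%s.csv", a)))
    }, character(1))
  )
  write_manifest(out_dir, config, settings, unname(files))
  invisible(list(results = results, league = league, files = files))
}

#' Run a one-way sensitivity analysis and write its report
#'
#' Writes `dsa_results.csv` (one row per parameter with both bounds and the
#' robust/sensitive conclusion), `tornado.csv` (ICER spans, dominance
#' bounds flagged), optionally `tornado.png`, and `manifest.json`.
#'
#' @param config Path to an input configuration.
#' @param dsa_spec Path to a sensitivity specification ([load_dsa_spec()]).
#' @param out_dir Output directory.
#' @param comparison Optional `c(intervention, comparator)` override of the
#'   spec's comparison.
#' @param figure Write the tornado figure (default `TRUE`; skipped with a
#'   message if no graphics device is available).
#' @return Invisibly, a list with `dsa`, `tornado` and `files`.
#' @export
write_dsa_report <- function(config, dsa_spec, out_dir, comparison = NULL,
                             figure = TRUE) {
  inputs <- load_inputs(config)
  spec <- load_dsa_spec(dsa_spec)
  comparison <- comparison %||% spec$comparison
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dsa <- run_dsa(inputs, spec$parameters, comparison)
  torn <- tornado(inputs, spec$parameters, comparison)
  files <- c(
    write_csv0(dsa, file.path(out_dir, "dsa_results.csv")),
    write_csv0(torn, file.path(out_dir, "tornado.csv"))
  )
  if (figure) {
    base <- attr(dsa, "base")
    fig <- file.path(out_dir, "tornado.png")
    ok <- tryCatch({
      ggplot2::ggsave(fig, plot_tornado(torn, base$icer),
                      width = 8, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      message("tornado figure skipped: ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, basename(fig))
  }
  write_manifest(out_dir, config, inputs$settings, unname(files))
  invisible(list(dsa = dsa, tornado = torn, files = files))
}

#' Run a threshold search and write `threshold.json`
#'
#' @param config Path to an input configuration.
#' @param path Dot-path of the input to vary.
#' @param comparison `c(intervention, comparator)`.
#' @param lo,hi Bracket (values, or factors with `scale = "factor"`).
#' @param out_dir Output directory.
#' @param scale See [threshold_search()].
#' @return Invisibly, the `threshold_result`.
#' @export
write_threshold_report <- function(config, path, comparison, lo, hi,
                                   out_dir, scale = "value") {
  inputs <- load_inputs(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- threshold_search(inputs, path, comparison, lo, hi, scale = scale)
  out <- list(
    path = res$path, cutoff = res$cutoff,
    cutoff_factor = res$cutoff_factor, direction = res$direction,
    icer_at_cutoff = res$icer_at_cutoff,
    verification = list(
      below = list(preferred = res$below$preferred,
                   decision = res$below$decision_at_wtp,
                   icer = res$below$icer),
      above = list(preferred = res$above$preferred,
                   decision = res$above$decision_at_wtp,
                   icer = res$above$icer)
    ),
    bracket = res$bracket, scale = res$scale
  )
  jsonlite::write_json(out, file.path(out_dir, "threshold.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, config, inputs$settings, "threshold.json")
  invisible(res)
}
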