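#' Run configuration for the end-to-end pipeline
#'
#' Bundles the parameter objects of every stage plus the analysis switches.
#' All defaults reproduce the standard analysis: off-body exclusion before
#' AI and data ratios, 75% data-ratio threshold, strict per-bin daytime
#' enforcement, Bonferroni family of 4 for the whole-attack analysis and
#' tests-performed for the onset-relative analysis.
#'
#' @param ai an [ai_params()].
#' @param wear a [wear_params()].
#' @param cal a [calendar_config()].
#' @param min_ratio data-ratio threshold (default 0.75).
#' @param strict_bin_daytime drop onset-relative bins overlapping nighttime.
#' @param whole_attack_family Bonferroni family size for the whole-attack
#'   analysis (default 4).
#' @param bin_family Bonferroni family size for the onset-relative
#'   analysis; `NULL` = number of tests performed.
#' @param stratify_treatment optional treatment label for a stratified
#'   re-analysis of whole attacks (e.g. `"oxygen"`).
#' @param run_offbody_detection run [detect_offbody()] before analysis
#'   (default `TRUE`).
#' @param onset_relative run the onset-relative analysis too (default
#'   `TRUE`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(ai = ai_params(), wear = wear_params(),
                       cal = calendar_config(), min_ratio = 0.75,
                       strict_bin_daytime = TRUE,
                       whole_attack_family = 4L, bin_family = NULL,
                       stratify_treatment = NULL,
                       run_offbody_detection = TRUE,
                       onset_relative = TRUE) {
  structure(list(ai = ai, wear = wear, cal = cal, min_ratio = min_ratio,
                 strict_bin_daytime = strict_bin_daytime,
                 whole_attack_family = whole_attack_family,
                 bin_family = bin_family,
                 stratify_treatment = stratify_treatment,
                 run_offbody_detection = run_offbody_detection,
                 onset_relative = onset_relative),
            class = "run_config")
}

#' Run the full event-locked analysis
#'
#' Orchestrates the stages in the canonical order: off-body detection,
#' AI computation, attack eligibility (daytime, data ratio, matched
#' intervals), whole-attack delta analysis, and (optionally) the
#' onset-relative analysis. Off-body exclusion precedes data ratios and AI
#' by construction. Deterministic: no randomness is consumed here.
#'
#' @param rec an [acc_recording()].
#' @param log an [event_log()].
#' @param config a [run_config()].
#' @return an object of class `actidelta_run`: list with `ledger`
#'   (eligibility funnel), `funnel` (named counts total / daytime /
#'   data_ok / eligible), `delta_table`, `stat_report`, `onset_relative`
#'   (sub-list or `NULL`), `stratified` (sub-list or `NULL`), `params`
#'   (every design parameter in force), and `explanation` when the
#'   eligible set is empty.
#' @export
run_pipeline <- function(rec, log, config = run_config()) {
  if (config$run_offbody_detection)
    rec <- apply_offbody_detection(rec, config$wear)
  ai <- compute_ai(rec, config$ai)
  elig <- attack_eligibility(log, rec, config$cal, config$min_ratio)
  whole <- analyze_whole_attacks(elig, ai, log,
                                 m = config$whole_attack_family)
  strat <- NULL
  if (!is.null(config$stratify_treatment))
    strat <- analyze_whole_attacks(elig, ai, log,
                                   m = config$whole_attack_family,
                                   treatment = config$stratify_treatment)
  onset <- NULL
  if (config$onset_relative)
    onset <- analyze_onset_relative(elig, ai, rec, log, config$cal,
                                    config$strict_bin_daytime,
                                    config$bin_family, config$min_ratio)
  st <- elig$ledger$status
  funnel <- c(total = length(st),
              daytime = sum(st != "nighttime"),
              data_ok = sum(!st %in% c("nighttime", "low_data_ratio")),
              eligible = sum(st == "eligible"))
  out <- list(ledger = elig$ledger, funnel = funnel,
              delta_table = whole$delta_table,
              stat_report = whole$stat_report,
              onset_relative = onset, stratified = strat,
              eligibility = elig, ai = ai,
              params = list(
                ai = unclass(config$ai), wear = unclass(config$wear),
                cal = list(nighttime = paste(config$cal$nighttime_start,
                                             config$cal$nighttime_end,
                                             sep = "-"),
                           n_holidays = length(config$cal$holiday_dates),
                           weekend_days = config$cal$weekend_days),
                min_ratio = config$min_ratio,
                strict_bin_daytime = config$strict_bin_daytime,
                whole_attack_family = config$whole_attack_family,
                bin_family = config$bin_family))
  if (!any(st == "eligible"))
    out$explanation <- "no attacks passed the eligibility rules"
  class(out) <- "actidelta_run"
  out
}

#' @export
print.actidelta_run <- function(x, ...) {
  cat("<actidelta_run>\n  funnel:",
      paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " -> "),
      "\n")
  if (nrow(x$stat_report)) {
    cat("  whole-attack tests:\n")
    print(x$stat_report, row.names = FALSE)
  } else cat("  ", x$explanation, "\n")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits the eligibility ledger, the delta table and the statistics report
#' as CSV, plus a JSON run log with every design-decision parameter in
#' force. Re-writing the same run produces byte-identical files.
#'
#' @param run an `actidelta_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_times <- function(df) {
    for (cl in names(df))
      if (inherits(df[[cl]], "POSIXct"))
        df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%S")
    df
  }
  data.table::fwrite(fmt_times(run$ledger), file.path(dir, "eligibility_ledger.csv"))
  data.table::fwrite(run$delta_table, file.path(dir, "delta_table.csv"))
  data.table::fwrite(run$stat_report, file.path(dir, "stat_report.csv"))
  if (!is.null(run$onset_relative)) {
    data.table::fwrite(run$onset_relative$delta_table,
                       file.path(dir, "onset_relative_delta_table.csv"))
    data.table::fwrite(run$onset_relative$stat_report,
                       file.path(dir, "onset_relative_stat_report.csv"))
    data.table::fwrite(run$onset_relative$skipped_bins,
                       file.path(dir, "skipped_bins.csv"))
  }
  jsonlite::write_json(
    c(run$params,
      list(funnel = as.list(run$funnel),
           explanation = if (is.null(run$explanation)) NULL else
             run$explanation)),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a flat config file whose keys mirror the arguments of
#' [run_config()], [ai_params()], [wear_params()] and [calendar_config()];
#' unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  take <- function(block, builder) {
    b <- raw[[block]]
    if (is.null(b)) return(builder())
    unknown <- setdiff(names(b), names(formals(builder)))
    if (length(unknown))
      stop("unknown ", block, " key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(b$holiday_dates)) b$holiday_dates <- as.Date(b$holiday_dates)
    do.call(builder, b)
  }
  top <- raw[setdiff(names(raw), c("ai", "wear", "cal"))]
  unknown <- setdiff(names(top),
                     setdiff(names(formals(run_config)), c("ai", "wear", "cal")))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, c(list(ai = take("ai", ai_params),
                             wear = take("wear", wear_params),
                             cal = take("cal", calendar_config)), top))
}
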