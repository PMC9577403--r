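#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis into one validated
#' list. Defaults mirror routine practice: case floor 3, comparison
#' thresholds 3/4/5/6/7/11, plain Pearson chi-square, BCPNN as the
#' comparison reference.
#'
#' @param input Path to the input line listing (CSV or XLSX), or — in
#'   `"printed"` mode — to a pre-computed statistics CSV in the layout of
#'   [screen_from_printed()].
#' @param mode `"full"` (compute statistics from the pair universe) or
#'   `"printed"` (classify and compare pre-computed statistics; used when
#'   the comparison denominators are unavailable).
#' @param column_map,delim Passed to [read_line_listing()].
#' @param drug_scope Optional drug names delimiting the screen.
#' @param exclude_combinations,fuzzy_duplicates Passed to
#'   [filter_reports()].
#' @param min_cases Case floor for [all_tables()].
#' @param thresholds Case-count thresholds for [compare_methods()].
#' @param yates Use Yates-corrected chi-square?
#' @param bcpnn_moments `"approximate"` or `"exact"` (see [bcpnn()]).
#' @param reference Reference method for the comparison.
#' @param exposure Optional exposure table (`drug`, `patients_exposed`).
#' @param total_reports Optional database-wide report count.
#' @param out_dir Output directory for exported files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, mode = c("full", "printed"), column_map = NULL,
                       delim = ";", drug_scope = NULL,
                       exclude_combinations = FALSE, fuzzy_duplicates = FALSE,
                       min_cases = 3L, thresholds = c(3L, 4L, 5L, 6L, 7L, 11L),
                       yates = FALSE,
                       bcpnn_moments = c("approximate", "exact"),
                       reference = "BCPNN", exposure = NULL,
                       total_reports = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  bcpnn_moments <- match.arg(bcpnn_moments)
  reference <- match.arg(reference, methods_all)
  structure(list(
    input = input, mode = mode, column_map = column_map, delim = delim,
    drug_scope = drug_scope, exclude_combinations = exclude_combinations,
    fuzzy_duplicates = fuzzy_duplicates, min_cases = min_cases,
    thresholds = thresholds, yates = yates, bcpnn_moments = bcpnn_moments,
    reference = reference, exposure = exposure,
    total_reports = total_reports, out_dir = out_dir
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are the
#'   arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("JSON configuration requires the 'jsonlite' package")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown configuration keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes ingest, exclusion filtering, pair expansion, contingency-table
#' construction, four-method signal detection, method comparison and
#' descriptive summaries; optionally exports every table and a run log.
#' All stages are deterministic, so re-running an identical configuration
#' reproduces identical outputs.
#'
#' In `"printed"` mode the input is a pre-computed statistics table and
#' only classification, comparison and export run.
#'
#' @param config A `run_config` list (see [run_config()],
#'   [read_run_config()]).
#' @return Invisibly, a list with (mode-dependent) elements `reports`,
#'   `pairs`, `tables`, `screen`, `comparison`, `descriptives`, `log`
#'   (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  echo <- config[!vapply(config, is.null, logical(1))]
  say("config: %s", paste(names(echo), vapply(echo, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=", collapse = "; "))

  res <- list()
  if (config$mode == "printed") {
    stats <- readr::read_csv(config$input, show_col_types = FALSE,
                             progress = FALSE)
    say("stage printed-statistics: %d combinations read", nrow(stats))
    screen <- screen_from_printed(stats, flags = "classified")
    res$screen <- screen
  } else {
    reports <- read_line_listing(config$input, column_map = config$column_map,
                                 delim = config$delim)
    rej <- rejected_rows(reports)
    say("stage ingest: %d reports read, %d rows rejected", nrow(reports),
        nrow(rej))
    for (i in seq_len(nrow(rej))) {
      say("  rejected row %d (%s): %s", rej$row[i], rej$report_id[i],
          rej$reason[i])
    }
    retained <- filter_reports(reports,
                               exclude_combinations = config$exclude_combinations,
                               fuzzy_duplicates = config$fuzzy_duplicates)
    excl <- exclusion_log(retained)
    say("stage filter: %d retained, %d excluded", nrow(retained), nrow(excl))
    for (i in seq_len(nrow(excl))) {
      say("  excluded %s: %s", excl$report_id[i], excl$reason[i])
    }
    pairs <- expand_pairs(retained, drug_scope = config$drug_scope)
    say("stage pairs: %d drug-event pairs", nrow(pairs))
    if (nrow(pairs) == 0L) abort("pipeline aborted at stage pairs: no pairs in scope")
    tables <- all_tables(pairs, min_cases = config$min_cases)
    say("stage tables: %d combinations with >= %d cases", nrow(tables),
        config$min_cases)
    screen <- detect_signals(tables, yates = config$yates,
                             bcpnn_moments = config$bcpnn_moments)
    res <- list(reports = retained, pairs = pairs, tables = tables,
                screen = screen)
    res$descriptives <- summarize_descriptives(
      retained, exposure = config$exposure,
      total_reports = config$total_reports
    )
  }
  say("stage detect: %d combinations screened, signals per method: %s",
      nrow(res$screen),
      paste(capture_counts(res$screen), collapse = ", "))
  res$comparison <- compare_methods(res$screen, reference = config$reference,
                                    thresholds = config$thresholds)
  say("stage compare: %d rows vs %s reference", nrow(res$comparison),
      config$reference)
  res$log <- log

  if (!is.null(config$out_dir)) {
    write_results(res, config$out_dir)
    say("stage export: results written to %s", config$out_dir)
    res$log <- log
  }
  invisible(res)
}

capture_counts <- function(screen) {
  fl <- signal_flags(screen)
  vapply(methods_all, function(m) sprintf("%s=%d", m, sum(fl[[m]])),
         character(1))
}

#' Export pipeline results to CSV files
#'
#' Writes one CSV per result table into `dir`: `pairs.csv`, `signals.csv`
#' (display precision, 2 decimals half-up) plus `signals_raw.csv` (full
#' precision), `comparison.csv` and `comparison_raw.csv`, descriptive
#' tables and the run log. Missing elements are skipped.
#'
#' @param results The list returned by [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(dir, name), na = "", progress = FALSE)
  }
  round2 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                    ~ round_half_up(.x, 2)))
  }
  if (!is.null(results$pairs)) w(results$pairs, "pairs.csv")
  if (!is.null(results$screen)) {
    w(round2(as_tibble(results$screen)), "signals.csv")
    w(as_tibble(results$screen), "signals_raw.csv")
  }
  if (!is.null(results$comparison)) {
    w(round2(as_tibble(results$comparison)), "comparison.csv")
    w(as_tibble(results$comparison), "comparison_raw.csv")
  }
  if (!is.null(results$descriptives)) {
    d <- results$descriptives
    w(d$overall, "descriptives_overall.csv")
    w(d$by_drug, "descriptives_by_drug.csv")
    w(d$sex, "descriptives_sex.csv")
    w(d$age_bands, "descriptives_age.csv")
  }
  if (!is.null(results$log)) {
    writeLines(results$log, file.path(dir, "run_log.txt"))
  }
  invisible(dir)
}
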