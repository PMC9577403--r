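#' Simulate spontaneous ADR reports with planted associations
#'
#' Generates a synthetic reporting database from a multinomial
#' drug-by-event model: each report draws one suspected drug from the drug
#' marginals, then draws its event(s) from the event marginals re-weighted,
#' for planted (drug, event) cells, by the configured relative risk and
#' renormalized within the drug. With all relative risks at 1 the table is
#' exchangeable and every combination is null; a cell planted at relative
#' risk `rr` has its reporting probability inflated `rr`-fold before
#' renormalization, so the PRR of that cell estimates approximately `rr`
#' for small baseline event probabilities.
#'
#' @param n_reports Number of reports to generate.
#' @param drugs Drug marginals: a character vector (uniform weights) or a
#'   data frame with columns `name`, `weight`.
#' @param events Event marginals: a character vector or a data frame with
#'   columns `pt`, `weight`.
#' @param planted Optional data frame of planted associations with columns
#'   `drug`, `event_pt`, `rr` (relative risk, >= 0).
#' @param events_per_report Either a single integer (every report lists
#'   exactly that many distinct events) or `c(mean, max)` for a
#'   zero-truncated Poisson capped at `max`.
#' @param multi_drug_prob Probability that a report lists a second
#'   suspected drug (default 0; used to exercise combination-report
#'   exclusion).
#' @param duplicate_prob Probability that a report is flagged duplicate.
#' @param uncertain_prob Probability that a report's certainty is
#'   `uncertain`.
#' @param seed Optional integer seed; a given seed reproduces the report
#'   list exactly.
#' @return A reports tibble in the format of [read_line_listing()].
#' @export
simulate_reports <- function(n_reports, drugs, events, planted = NULL,
                             events_per_report = 1L, multi_drug_prob = 0,
                             duplicate_prob = 0, uncertain_prob = 0,
                             seed = NULL) {
  stopifnot(n_reports >= 1L)
  if (!is.null(seed)) withr::local_seed(seed)
  drugs <- as_marginals(drugs, c("name", "weight"))
  events <- as_marginals(events, c("pt", "weight"))
  if (any(drugs$weight <= 0) || any(events$weight <= 0)) {
    abort("marginal weights must be positive")
  }

  # per-drug event distribution: baseline weights times planted relative risks
  event_w <- matrix(events$weight, nrow = nrow(drugs), ncol = nrow(events),
                    byrow = TRUE, dimnames = list(drugs$name, events$pt))
  if (!is.null(planted) && nrow(planted) > 0L) {
    stopifnot(all(c("drug", "event_pt", "rr") %in% names(planted)))
    if (any(!is.finite(planted$rr)) || any(planted$rr < 0)) {
      abort("planted relative risks must be finite and nonnegative")
    }
    for (i in seq_len(nrow(planted))) {
      di <- match(planted$drug[i], drugs$name)
      ei <- match(planted$event_pt[i], events$pt)
      if (is.na(di) || is.na(ei)) {
        abort("planted cell names an unknown drug or event")
      }
      event_w[di, ei] <- event_w[di, ei] * planted$rr[i]
    }
    if (any(rowSums(event_w) == 0)) {
      abort("a drug's event distribution is degenerate (all-zero weights)")
    }
  }

  drug_idx <- sample.int(nrow(drugs), n_reports, replace = TRUE,
                         prob = drugs$weight)
  k <- if (length(events_per_report) == 1L) {
    rep(as.integer(events_per_report), n_reports)
  } else {
    pmin(pmax(1L, rpois(n_reports, events_per_report[1])),
         as.integer(events_per_report[2]))
  }
  second <- runif(n_reports) < multi_drug_prob

  rows <- lapply(seq_len(n_reports), function(i) {
    di <- drug_idx[i]
    d <- tibble(drug_name = drugs$name[di], drug_role = "first_suspected")
    if (second[i] && nrow(drugs) > 1L) {
      alt <- sample.int(nrow(drugs), 1L, prob = replace(drugs$weight, di, 0))
      d <- bind_rows(d, tibble(drug_name = drugs$name[alt],
                               drug_role = "suspected"))
    }
    ei <- sample.int(nrow(events), min(k[i], nrow(events)),
                     replace = FALSE, prob = event_w[di, ])
    tibble(
      report_id = sprintf("synth-%06d", i),
      report_date = as.Date(NA), age_years = NA_real_, sex = "unknown",
      certainty = if (runif(1) < uncertain_prob) "uncertain" else "certain",
      is_duplicate = runif(1) < duplicate_prob,
      drugs = list(d),
      events = list(tibble(event_pt = events$pt[ei], event_soc = NA_character_,
                           serious = FALSE))
    )
  })
  bind_rows(rows)
}

as_marginals <- function(x, cols) {
  if (is.character(x)) {
    x <- as_tibble(setNames(list(x, rep(1, length(x))), cols))
  }
  x <- as_tibble(x)
  stopifnot(all(cols %in% names(x)))
  x[cols]
}

#' Simulate directly at the drug-event pair level
#'
#' A fast path for simulation studies that need only the pair table:
#' equivalent to `expand_pairs(simulate_reports(...))` for one-drug,
#' fixed-one-event reports, but vectorized.
#'
#' @inheritParams simulate_reports
#' @return A pair tibble (see [expand_pairs()]).
#' @export
simulate_pairs <- function(n_reports, drugs, events, planted = NULL,
                           seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  drugs <- as_marginals(drugs, c("name", "weight"))
  events <- as_marginals(events, c("pt", "weight"))
  event_w <- matrix(events$weight, nrow = nrow(drugs), ncol = nrow(events),
                    byrow = TRUE)
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      di <- match(planted$drug[i], drugs$name)
      ei <- match(planted$event_pt[i], events$pt)
      event_w[di, ei] <- event_w[di, ei] * planted$rr[i]
    }
  }
  di <- sample.int(nrow(drugs), n_reports, replace = TRUE, prob = drugs$weight)
  ei <- integer(n_reports)
  for (d in unique(di)) {
    idx <- which(di == d)
    ei[idx] <- sample.int(nrow(events), length(idx), replace = TRUE,
                          prob = event_w[d, ])
  }
  tibble(
    drug = drugs$name[di], event_pt = events$pt[ei],
    event_soc = NA_character_, serious = FALSE,
    report_id = sprintf("synth-%06d", seq_len(n_reports))
  )
}

#' Load a packaged fluoroquinolone fixture table
#'
#' Machine-readable transcriptions of the published summary tables of a
#' single-hospital fluoroquinolone spontaneous-reporting screen
#' (levofloxacin, moxifloxacin, ciprofloxacin), shipped with the package:
#'
#' * `"exposure"` — per-drug ADR report counts, serious counts, number of
#'   patients exposed, and ADR incidence.
#' * `"soc_counts"` — drug-event pair counts per system organ class
#'   (27 drug-SOC cells summing to 391 pairs).
#' * `"printed_stats"` — the 31 screened drug-event combinations with
#'   their published statistics (PRR/ROR with 95% CIs, chi-square, IC with
#'   interval) and published per-method determinations.
#' * `"method_comparison"` — the published comparison of PRR/ROR/MHRA
#'   against the BCPNN reference across case-count thresholds.
#'
#' @param name One of `"exposure"`, `"soc_counts"`, `"printed_stats"`,
#'   `"method_comparison"`.
#' @return A typed tibble.
#' @export
load_fixture <- function(name = c("exposure", "soc_counts", "printed_stats",
                                  "method_comparison")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("fluoroquinolone_", name, ".csv"),
                      package = "pvsignals", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "printed_stats") {
    out <- out %>% mutate(
      dplyr::across(dplyr::all_of(c("mhra_signal", "prr_signal", "ror_signal")),
                    as_flag),
      bcpnn_strength = factor(.data$bcpnn_strength, levels = strength_levels,
                              ordered = TRUE)
    )
  }
  out
}

#' Reconstruct the fixture pair table from the published SOC counts
#'
#' Expands the `"soc_counts"` fixture (pair counts per drug and system
#' organ class) into an explicit drug-event pair table: each drug-SOC cell
#' contributes `cases` pairs whose event is recorded at SOC level. Report
#' ids are synthetic placeholders — the underlying reports are not
#' published — so the table supports pair-level counting (margins, SOC
#' matrices), not report-level deduplication.
#'
#' @return A pair tibble (see [expand_pairs()]) with 391 rows.
#' @export
fixture_pairs <- function() {
  soc <- load_fixture("soc_counts")
  out <- soc %>%
    filter(.data$cases > 0) %>%
    tidyr::uncount(.data$cases) %>%
    mutate(event_pt = .data$soc, event_soc = .data$soc, serious = FALSE,
           report_id = sprintf("fq-pair-%03d", row_number())) %>%
    select("drug", "event_pt", "event_soc", "serious", "report_id")
  out
}

#' Reconstruct the fixture report set from the published exposure table
#'
#' Builds a one-drug-one-event report per reported ADR case of the
#' `"exposure"` fixture, with serious flags distributed per its serious
#' counts: enough to reproduce every published report-level descriptive
#' (per-drug counts and shares, serious proportion, incidence). Ages, sex
#' and event terms are not published at report level and are left
#' unknown/placeholder.
#'
#' @return A reports tibble (see [read_line_listing()]) with one row per
#'   reported case.
#' @export
fixture_reports <- function() {
  exp_tbl <- load_fixture("exposure")
  rows <- lapply(seq_len(nrow(exp_tbl)), function(i) {
    k <- exp_tbl$adr_cases[i]
    ks <- exp_tbl$serious_cases[i]
    tibble(
      report_id = sprintf("fq-%s-%03d", substr(exp_tbl$drug[i], 1, 3),
                          seq_len(k)),
      report_date = as.Date(NA), age_years = NA_real_, sex = "unknown",
      certainty = "probable", is_duplicate = FALSE,
      drugs = lapply(seq_len(k), function(j) {
        tibble(drug_name = exp_tbl$drug[i], drug_role = "first_suspected")
      }),
      events = lapply(seq_len(k), function(j) {
        tibble(event_pt = "adverse reaction", event_soc = NA_character_,
               serious = j <= ks)
      })
    )
  })
  bind_rows(rows)
}
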