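#' Descriptive summaries of a report set
#'
#' Computes the standard descriptive tables of a spontaneous-reporting
#' screen. Each report is attributed to one drug — its first drug in the
#' `first_suspected` role, falling back to the first listed drug — and a
#' report is serious when any of its events is flagged serious.
#'
#' @param reports A validated reports tibble.
#' @param exposure Optional data frame `drug`, `patients_exposed` used to
#'   derive per-drug ADR incidence (reports / patients exposed); drugs
#'   without an exposure figure get `NA` incidence.
#' @param total_reports Optional integer: size of the whole reporting
#'   database, used to express the report set as a share of the total.
#' @return A list of class `adr_descriptives`:
#' \describe{
#'   \item{overall}{one row: `n_reports`, `n_serious`, `serious_pct`,
#'     `total_reports`, `share_pct`.}
#'   \item{by_drug}{per attributed drug: `n_reports`, `pct` (of the report
#'     set), `n_serious`, `serious_pct` (of all serious reports),
#'     `patients_exposed`, `incidence`.}
#'   \item{sex}{counts and percentages by sex.}
#'   \item{age_bands}{counts and percentages for <18, 18-40, 41-65, >65
#'     and unknown.}
#' }
#' Percentages are kept at full precision; [print.adr_descriptives()] and
#' the CSV export round to 2 decimals (half-up).
#' @export
summarize_descriptives <- function(reports, exposure = NULL,
                                   total_reports = NULL) {
  n <- nrow(reports)
  attributed <- vapply(reports$drugs, function(d) {
    if (nrow(d) == 0L) return(NA_character_)
    fs <- d$drug_name[d$drug_role == "first_suspected"]
    if (length(fs) > 0L) fs[1] else d$drug_name[1]
  }, character(1))
  serious <- vapply(reports$events, function(e) any(e$serious), logical(1))
  n_serious <- sum(serious)

  overall <- tibble(
    n_reports = n, n_serious = n_serious,
    serious_pct = if (n > 0) 100 * n_serious / n else NA_real_,
    total_reports = total_reports %||% NA_integer_,
    share_pct = if (!is.null(total_reports)) 100 * n / total_reports
                else NA_real_
  )

  by_drug <- tibble(drug = attributed, serious = serious) %>%
    filter(!is.na(.data$drug)) %>%
    group_by(.data$drug) %>%
    summarise(n_reports = n(), n_serious = sum(.data$serious),
              .groups = "drop") %>%
    mutate(pct = if (n > 0) 100 * .data$n_reports / n else NA_real_,
           serious_pct = if (.env$n_serious > 0) {
             100 * .data$n_serious / .env$n_serious
           } else NA_real_) %>%
    arrange(desc(.data$n_reports))
  if (!is.null(exposure)) {
    exposure <- as_tibble(exposure) %>%
      mutate(drug = tolower(.data$drug)) %>%
      select("drug", "patients_exposed")
    by_drug <- by_drug %>%
      left_join(exposure, by = "drug") %>%
      mutate(incidence = .data$n_reports / .data$patients_exposed)
  } else {
    by_drug$patients_exposed <- NA_real_
    by_drug$incidence <- NA_real_
  }
  by_drug <- by_drug %>% select("drug", "n_reports", "pct", "n_serious",
                                "serious_pct", "patients_exposed", "incidence")

  sex <- tibble(sex = if (n > 0) reports$sex else character()) %>%
    count(.data$sex, name = "n_reports") %>%
    mutate(pct = 100 * .data$n_reports / n)

  band <- cut(reports$age_years, breaks = c(-Inf, 17, 40, 65, Inf),
              labels = c("<18", "18-40", "41-65", ">65"))
  band <- factor(ifelse(is.na(band), "unknown", as.character(band)),
                 levels = c("<18", "18-40", "41-65", ">65", "unknown"))
  age_bands <- tibble(age_band = band[seq_len(n)]) %>%
    count(.data$age_band, name = "n_reports", .drop = FALSE) %>%
    mutate(pct = if (n > 0) 100 * .data$n_reports / n else NA_real_)

  structure(list(overall = overall, by_drug = by_drug, sex = sex,
                 age_bands = age_bands),
            class = "adr_descriptives")
}

#' @export
print.adr_descriptives <- function(x, ...) {
  round2 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                    ~ round_half_up(.x, 2)))
  }
  cat("Spontaneous-report descriptives\n\nOverall:\n")
  print(round2(x$overall))
  cat("\nBy drug:\n")
  print(dplyr::mutate(round2(x$by_drug),
                      incidence = round_half_up(x$by_drug$incidence, 4)))
  cat("\nSex:\n")
  print(round2(x$sex))
  cat("\nAge bands:\n")
  print(round2(x$age_bands))
  invisible(x)
}

# round() uses banker's rounding; displayed percentages follow the
# half-up convention instead
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Drug-by-SOC pair-count matrix
#'
#' Cross-tabulates drug-event pairs by drug and system organ class, the
#' standard body-system overview of a screen.
#'
#' @param pairs A pair tibble with a non-empty `event_soc` column.
#' @return A tibble with one row per SOC and one count column per drug,
#'   plus a `total` column; pairs lacking a SOC are grouped under
#'   `"(unclassified)"`.
#' @export
soc_matrix <- function(pairs) {
  pairs %>%
    mutate(event_soc = ifelse(is.na(.data$event_soc) | .data$event_soc == "",
                              "(unclassified)", .data$event_soc)) %>%
    count(.data$event_soc, .data$drug) %>%
    tidyr::pivot_wider(names_from = "drug", values_from = "n",
                       values_fill = 0L) %>%
    mutate(total = rowSums(dplyr::pick(dplyr::where(is.numeric)))) %>%
    rename(soc = "event_soc")
}
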