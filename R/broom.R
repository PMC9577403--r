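#' Tidy a signal screen into long method-per-row form
#'
#' @param x A `signal_screen`.
#' @param ... Unused.
#' @return A tibble with one row per combination and method: `drug`,
#'   `event_pt`, `n_cases`, `method`, `point`, `lower`, `upper`,
#'   `strength`, `signal`. For MHRA `point` is the chi-square and the
#'   interval is `NA`.
#' @method tidy signal_screen
#' @export
tidy.signal_screen <- function(x, ...) {
  pick <- function(method, point, lower, upper, strength) {
    tibble(drug = x$drug, event_pt = x$event_pt, n_cases = x$a,
           method = method, point = point, lower = lower, upper = upper,
           strength = strength, signal = strength != "none")
  }
  bind_rows(
    pick("PRR", x$prr, x$prr_low, x$prr_high, x$prr_strength),
    pick("ROR", x$ror, x$ror_low, x$ror_high, x$ror_strength),
    pick("MHRA", x$chi2, NA_real_, NA_real_, x$mhra_strength),
    pick("BCPNN", x$ic, x$ic_low, x$ic_high, x$bcpnn_strength)
  ) %>%
    mutate(method = factor(.data$method, levels = methods_all)) %>%
    arrange(.data$method, .data$drug, desc(.data$n_cases), .data$event_pt)
}

#' One-line summary of a signal screen
#'
#' @param x A `signal_screen`.
#' @param ... Unused.
#' @return A one-row tibble: `n_combinations`, `n_drugs` and the signal
#'   count per method (`prr_signals`, `ror_signals`, `mhra_signals`,
#'   `bcpnn_signals`).
#' @method glance signal_screen
#' @export
glance.signal_screen <- function(x, ...) {
  fl <- signal_flags(x)
  tibble(
    n_combinations = nrow(x),
    n_drugs = dplyr::n_distinct(x$drug),
    prr_signals = sum(fl$PRR), ror_signals = sum(fl$ROR),
    mhra_signals = sum(fl$MHRA), bcpnn_signals = sum(fl$BCPNN)
  )
}

#' Tidy a method comparison
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble in long metric form: `method`,
#'   `min_cases`, `sample_size`, `metric`, `value`.
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(dplyr::all_of(c("sensitivity", "specificity", "ppv",
                                        "npv", "youden")),
                        names_to = "metric", values_to = "value") %>%
    select("method", "min_cases", "sample_size", "metric", "value")
}

#' One-row-per-method summary of a comparison (threshold-sweep AUC)
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return A tibble `method`, `auc` (anchored trapezoid over the sweep's
#'   ROC points), `reference`.
#' @method glance method_comparison
#' @export
glance.method_comparison <- function(x, ...) {
  roc_auc(x) %>% mutate(reference = attr(x, "reference") %||% NA_character_)
}
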