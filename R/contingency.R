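#' Build the 2x2 contingency table for one drug-event combination
#'
#' Disproportionality statistics are computed from a 2x2 table over a pair
#' universe: `a` = pairs with the target drug and target event, `b` = target
#' drug with other events, `c` = other drugs with the target event, `d` =
#' everything else. The full pair list passed in *is* the universe, so
#' `a + b + c + d` always equals the number of pairs.
#'
#' @param pairs A pair tibble (see [expand_pairs()]); the comparison
#'   universe.
#' @param drug Target drug generic name (matched case-insensitively).
#' @param event_pt Target event preferred term (matched case-insensitively).
#' @return A one-row tibble: `drug`, `event_pt`, `a`, `b`, `c`, `d`, `n`.
#'   A drug or event absent from the universe is valid and yields `a = 0`.
#' @export
build_table <- function(pairs, drug, event_pt) {
  stopifnot(nrow(pairs) >= 1L)
  pd <- tolower(pairs$drug)
  pe <- tolower(pairs$event_pt)
  is_d <- pd == tolower(drug)
  is_e <- pe == tolower(event_pt)
  tibble(
    drug = drug, event_pt = event_pt,
    a = sum(is_d & is_e), b = sum(is_d & !is_e),
    c = sum(!is_d & is_e), d = sum(!is_d & !is_e),
    n = nrow(pairs)
  )
}

#' Contingency tables for all drug-event combinations
#'
#' One 2x2 table per distinct (drug, event) combination occurring at least
#' `min_cases` times, computed against the full pair list as the comparison
#' universe. The conventional screening floor is 3 cases: combinations
#' reported fewer than 3 times are too sparse for any of the four
#' disproportionality criteria.
#'
#' @param pairs A pair tibble.
#' @param min_cases Minimum case count `a` for a combination to be
#'   retained (default 3).
#' @return A tibble with columns `drug`, `event_pt`, `a`, `b`, `c`, `d`,
#'   `n`, ordered by drug, then descending `a`, then event.
#' @export
all_tables <- function(pairs, min_cases = 3L) {
  stopifnot(min_cases >= 1L)
  if (nrow(pairs) == 0L) {
    return(tibble(drug = character(), event_pt = character(),
                  a = integer(), b = integer(), c = integer(),
                  d = integer(), n = integer()))
  }
  n_total <- nrow(pairs)
  pairs2 <- pairs %>% mutate(drug = tolower(.data$drug),
                             event_pt = tolower(.data$event_pt))
  drug_margin <- pairs2 %>% count(.data$drug, name = "n_drug")
  event_margin <- pairs2 %>% count(.data$event_pt, name = "n_event")
  pairs2 %>%
    count(.data$drug, .data$event_pt, name = "a") %>%
    left_join(drug_margin, by = "drug") %>%
    left_join(event_margin, by = "event_pt") %>%
    mutate(
      b = .data$n_drug - .data$a,
      c = .data$n_event - .data$a,
      d = n_total - .data$a - .data$b - .data$c,
      n = n_total
    ) %>%
    filter(.data$a >= min_cases) %>%
    arrange(.data$drug, desc(.data$a), .data$event_pt) %>%
    select("drug", "event_pt", "a", "b", "c", "d", "n")
}
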