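#' Proportional reporting ratio (PRR)
#'
#' PRR compares the proportion of a drug's reports naming the target event
#' with the same proportion among all other drugs:
#' \deqn{PRR = \frac{a/(a+b)}{c/(c+d)}}
#' The 95% confidence interval is the log-scale Wald interval
#' \eqn{\exp(\ln PRR \pm 1.96\,SE)} with
#' \eqn{SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}}.
#'
#' Zero-cell policy: a zero in `c` (or `d`) makes the statistic or its SE
#' undefined; 0.5 is then added to all four cells (Haldane–Anscombe) and
#' `corrected` is set. `a = 0` yields a point estimate of 0 with lower
#' bound 0 and can never signal.
#'
#' @param tables A contingency tibble (rows from [build_table()] /
#'   [all_tables()]).
#' @return A tibble with one row per input table: `drug`, `event_pt`,
#'   `n_cases`, `method`, `point`, `lower`, `upper`, `corrected`,
#'   `strength` (see [classify_signal()]) and `signal`.
#' @export
prr <- function(tables) {
  check_margins(tables, need_all = FALSE)
  with(tables, {
    corr <- (a > 0) & (b == 0 | c == 0 | d == 0)
    a2 <- a + 0.5 * corr; b2 <- b + 0.5 * corr
    c2 <- c + 0.5 * corr; d2 <- d + 0.5 * corr
    point <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
    se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
    lower <- exp(log(point) - qnorm(0.975) * se)
    upper <- exp(log(point) + qnorm(0.975) * se)
    zero <- a == 0
    point[zero] <- 0; lower[zero] <- 0; upper[zero] <- NA_real_
    signal_tbl(tables, "PRR", point, lower, upper, corrected = corr & !zero)
  })
}

#' Reporting odds ratio (ROR)
#'
#' The odds-ratio analogue of the PRR on the same 2x2 table:
#' \deqn{ROR = \frac{ad}{bc}}
#' with log-scale Wald 95% interval using
#' \eqn{SE = \sqrt{1/a + 1/b + 1/c + 1/d}}. Zero-cell policy as in [prr()].
#'
#' @inheritParams prr
#' @inherit prr return
#' @export
ror <- function(tables) {
  check_margins(tables, need_all = FALSE)
  with(tables, {
    corr <- (a > 0) & (b == 0 | c == 0 | d == 0)
    a2 <- a + 0.5 * corr; b2 <- b + 0.5 * corr
    c2 <- c + 0.5 * corr; d2 <- d + 0.5 * corr
    point <- (a2 * d2) / (b2 * c2)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
    lower <- exp(log(point) - qnorm(0.975) * se)
    upper <- exp(log(point) + qnorm(0.975) * se)
    zero <- a == 0
    point[zero] <- 0; lower[zero] <- 0; upper[zero] <- NA_real_
    signal_tbl(tables, "ROR", point, lower, upper, corrected = corr & !zero)
  })
}

#' MHRA criterion (PRR + case count + Pearson chi-square)
#'
#' The MHRA spontaneous-reporting criterion flags a combination when all of
#' PRR >= 2, case count >= 3 and Pearson \eqn{\chi^2 \ge 4} hold, where
#' \deqn{\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}.}
#' Signal strength is banded on \eqn{\chi^2} (see [classify_signal()]).
#'
#' @inheritParams prr
#' @param yates Apply Yates' continuity correction
#'   (\eqn{|ad-bc|} replaced by \eqn{\max(0, |ad-bc| - N/2)})? Default
#'   `FALSE` (plain Pearson).
#' @return As [prr()], with `point` holding \eqn{\chi^2} and the PRR point
#'   estimate carried in column `prr_point`; `lower`/`upper` are `NA`
#'   (the criterion has no interval).
#' @export
mhra <- function(tables, yates = FALSE) {
  check_margins(tables, need_all = TRUE)
  with(tables, {
    # doubles throughout: margin products overflow 32-bit integers
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    N <- a + b + c + d
    dev <- abs(a * d - b * c)
    if (yates) dev <- pmax(0, dev - N / 2)
    chi2 <- N * dev^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    prr_pt <- prr(tables)$point
    out <- signal_tbl(tables, "MHRA", chi2, NA_real_, NA_real_,
                      corrected = rep(yates, length(chi2)))
    out$prr_point <- prr_pt
    out$strength <- classify_signal("MHRA", chi2 = chi2, prr_point = prr_pt,
                                    n_cases = a)
    out$signal <- out$strength != "none"
    out
  })
}

#' BCPNN information component (IC)
#'
#' The Bayesian confidence propagation neural network measures
#' disproportionality as the information component
#' \eqn{IC = \log_2 \frac{p_{11}}{p_{1+} p_{+1}}}, the shrunk log2
#' observed-to-expected ratio of the drug-event cell under a Bayesian model
#' with Beta priors on the cell and margin probabilities
#' (\eqn{\alpha_1 = \beta_1 = 1}, \eqn{\alpha = \beta = 2},
#' \eqn{\gamma_{11} = 1}, the standard parameterization in hospital
#' pharmacovigilance systems). With \eqn{c_{11} = a}, \eqn{c_x = a+b},
#' \eqn{c_y = a+c}, \eqn{C = N} and
#' \eqn{\gamma = (C+2)^2 / ((c_x+1)(c_y+1))}:
#'
#' \deqn{IC = \log_2 \frac{(c_{11}+1)(C+2)^2}{(C+\gamma)(c_x+1)(c_y+1)}}
#' \deqn{V(IC) = \frac{1}{\ln^2 2}\left[
#'   \frac{C-c_{11}+\gamma-1}{(c_{11}+1)(1+C+\gamma)} +
#'   \frac{C-c_x+1}{(c_x+1)(C+3)} +
#'   \frac{C-c_y+1}{(c_y+1)(C+3)} \right]}
#'
#' These classical expressions (`moments = "approximate"`, the default and
#' the form used by the field's implementations) are a log-of-means
#' approximation to the posterior moments of IC; `moments = "exact"`
#' instead returns the exact posterior mean and SD of IC under the same
#' independent-Beta posterior, via digamma/trigamma functions. The two
#' agree to O(1/a); they differ noticeably only for very small case counts.
#'
#' The reported interval is \eqn{IC \pm 2 SD}; a signal requires its lower
#' limit \eqn{IC - 2SD > 0}.
#'
#' @inheritParams prr
#' @param moments `"approximate"` (classical closed form) or `"exact"`
#'   (exact posterior moments of IC).
#' @return As [prr()], with `point` = IC (bits), `lower`/`upper` =
#'   IC -/+ 2 SD, and the posterior SD in column `ic_sd`.
#' @export
bcpnn <- function(tables, moments = c("approximate", "exact")) {
  moments <- match.arg(moments)
  stopifnot(nrow(tables) >= 0)
  with(tables, {
    C <- a + b + c + d
    cx <- a + b
    cy <- a + c
    g <- (C + 2)^2 / ((cx + 1) * (cy + 1))
    if (moments == "approximate") {
      ic <- log2((a + 1) * (C + 2)^2 / ((C + g) * (cx + 1) * (cy + 1)))
      v <- (1 / log(2))^2 * (
        (C - a + g - 1) / ((a + 1) * (1 + C + g)) +
          (C - cx + 1) / ((cx + 1) * (C + 3)) +
          (C - cy + 1) / ((cy + 1) * (C + 3))
      )
    } else {
      # exact moments of log2 p11 - log2 px - log2 py under the posterior
      # p11 ~ Beta(a+1, C-a+g-1), px ~ Beta(cx+1, C-cx+1), py ~ Beta(cy+1, C-cy+1)
      ic <- (digamma(a + 1) - digamma(C + g) -
               digamma(cx + 1) + digamma(C + 2) -
               digamma(cy + 1) + digamma(C + 2)) / log(2)
      v <- (trigamma(a + 1) - trigamma(C + g) +
              trigamma(cx + 1) - trigamma(C + 2) +
              trigamma(cy + 1) - trigamma(C + 2)) / log(2)^2
    }
    sd <- sqrt(v)
    out <- signal_tbl(tables, "BCPNN", ic, ic - 2 * sd, ic + 2 * sd,
                      corrected = rep(FALSE, length(ic)))
    out$ic_sd <- sd
    out
  })
}

check_margins <- function(tables, need_all) {
  with(tables, {
    if (any(a + b == 0) || any(c + d == 0)) {
      abort("degenerate margin: a+b and c+d must both be positive")
    }
    if (need_all && (any(a + c == 0) || any(b + d == 0))) {
      abort("degenerate margin: all four margins must be positive for chi-square")
    }
  })
  invisible(tables)
}

signal_tbl <- function(tables, method, point, lower, upper, corrected) {
  out <- tibble(
    drug = tables$drug, event_pt = tables$event_pt, n_cases = tables$a,
    method = method, point = point, lower = lower, upper = upper,
    corrected = corrected
  )
  out$strength <- classify_signal(method, lower = lower, n_cases = tables$a)
  out$signal <- out$strength != "none"
  out
}

#' Classify signal strength
#'
#' Applies the standard signal-generation conditions and strength bands:
#'
#' * **PRR / ROR** — signal when the 95% CI lower bound exceeds 1 and the
#'   case count is at least 3; weak `(+)` for lower bound in (1, 50),
#'   medium `(++)` in \[50, 1000), high `(+++)` at or above 1000.
#' * **MHRA** — signal when PRR >= 2, cases >= 3 and \eqn{\chi^2 \ge 4};
#'   weak for \eqn{\chi^2} in \[4, 100), medium in \[100, 1000), high at
#'   or above 1000.
#' * **BCPNN** — no signal when IC - 2SD <= 0; weak in (0, 1.5], medium in
#'   (1.5, 3], high above 3.
#'
#' All comparisons against 1 (PRR/ROR) and 0 (BCPNN) are strict.
#'
#' @param method One of `"PRR"`, `"ROR"`, `"MHRA"`, `"BCPNN"`.
#' @param lower Interval lower bound (PRR/ROR 95% CI lower bound, or
#'   BCPNN IC - 2SD). Ignored for MHRA.
#' @param chi2 Pearson chi-square (MHRA only).
#' @param prr_point PRR point estimate (MHRA only).
#' @param n_cases Case count `a` (PRR/ROR/MHRA).
#' @return A factor with levels `none < weak < medium < high`.
#' @export
classify_signal <- function(method, lower = NULL, chi2 = NULL,
                            prr_point = NULL, n_cases = NULL) {
  method <- match.arg(method, methods_all)
  len <- max(length(lower), length(chi2), length(prr_point), length(n_cases), 1L)
  if (is.null(lower)) lower <- rep(NA_real_, len)
  if (is.null(chi2)) chi2 <- rep(NA_real_, len)
  if (is.null(prr_point)) prr_point <- rep(NA_real_, len)
  if (is.null(n_cases)) n_cases <- rep(NA_integer_, len)
  band <- function(x, cuts) {
    # cuts = c(weak_from, medium_from, high_from); x already gated
    ifelse(x >= cuts[3], "high", ifelse(x >= cuts[2], "medium", "weak"))
  }
  out <- if (method %in% c("PRR", "ROR")) {
    gate <- !is.na(lower) & lower > 1 & n_cases >= 3
    ifelse(gate, band(lower, c(1, 50, 1000)), "none")
  } else if (method == "MHRA") {
    gate <- !is.na(chi2) & !is.na(prr_point) &
      prr_point >= 2 & n_cases >= 3 & chi2 >= 4
    ifelse(gate, band(chi2, c(4, 100, 1000)), "none")
  } else {
    gate <- !is.na(lower) & lower > 0
    ifelse(gate, ifelse(lower > 3, "high",
                        ifelse(lower > 1.5, "medium", "weak")), "none")
  }
  factor(out, levels = strength_levels, ordered = TRUE)
}

#' Run all four disproportionality methods over a set of tables
#'
#' Computes PRR, ROR, the MHRA criterion and the BCPNN information
#' component for every contingency table and assembles a wide
#' signal-screen table, one row per drug-event combination. Combinations
#' with degenerate margins (a zero row or column total, for which the
#' frequentist statistics are undefined) are retained as flagged rows with
#' `NA` statistics and an explanatory `note` rather than aborting the
#' batch; the BCPNN IC, which is defined for every nonnegative table, is
#' still computed for them.
#'
#' @param tables A contingency tibble from [all_tables()].
#' @param yates Passed to [mhra()].
#' @param bcpnn_moments Passed to [bcpnn()].
#' @return A `signal_screen` tibble ordered by (drug, descending case
#'   count, event), with columns `drug`, `event_pt`, `a`..`d`, `n`, the
#'   per-method statistics (`prr`, `prr_low`, `prr_high`, `prr_strength`,
#'   analogous `ror_*`, `chi2`, `mhra_prr`, `mhra_strength`, `ic`,
#'   `ic_sd`, `ic_low`, `ic_high`, `bcpnn_strength`) and `note`.
#' @seealso [tidy.signal_screen()], [glance.signal_screen()],
#'   [compare_methods()]
#' @export
detect_signals <- function(tables, yates = FALSE,
                           bcpnn_moments = c("approximate", "exact")) {
  bcpnn_moments <- match.arg(bcpnn_moments)
  if (nrow(tables) == 0L) return(new_signal_screen(empty_screen()))
  tables <- tables %>% arrange(.data$drug, desc(.data$a), .data$event_pt)
  ok <- with(tables, a + b > 0 & c + d > 0 & a + c > 0 & b + d > 0)
  valid <- tables[ok, , drop = FALSE]

  base <- tables %>% select("drug", "event_pt", "a", "b", "c", "d", "n")
  bc <- bcpnn(tables, moments = bcpnn_moments)
  base$ic <- bc$point
  base$ic_sd <- bc$ic_sd
  base$ic_low <- bc$lower
  base$ic_high <- bc$upper
  base$bcpnn_strength <- bc$strength

  num_cols <- c("prr", "prr_low", "prr_high", "ror", "ror_low", "ror_high",
                "chi2", "mhra_prr")
  for (col in num_cols) base[[col]] <- NA_real_
  none <- factor("none", levels = strength_levels, ordered = TRUE)
  base$prr_strength <- rep(none, nrow(base))
  base$ror_strength <- rep(none, nrow(base))
  base$mhra_strength <- rep(none, nrow(base))
  base$note <- ifelse(ok, NA_character_, "degenerate margin: PRR/ROR/chi2 undefined")

  if (nrow(valid) > 0L) {
    p <- prr(valid); r <- ror(valid); m <- mhra(valid, yates = yates)
    base$prr[ok] <- p$point; base$prr_low[ok] <- p$lower; base$prr_high[ok] <- p$upper
    base$prr_strength[ok] <- p$strength
    base$ror[ok] <- r$point; base$ror_low[ok] <- r$lower; base$ror_high[ok] <- r$upper
    base$ror_strength[ok] <- r$strength
    base$chi2[ok] <- m$point; base$mhra_prr[ok] <- m$prr_point
    base$mhra_strength[ok] <- m$strength
  }
  base <- base %>% select(
    "drug", "event_pt", "a", "b", "c", "d", "n",
    "prr", "prr_low", "prr_high", "prr_strength",
    "ror", "ror_low", "ror_high", "ror_strength",
    "chi2", "mhra_prr", "mhra_strength",
    "ic", "ic_sd", "ic_low", "ic_high", "bcpnn_strength", "note"
  )
  new_signal_screen(base)
}

empty_screen <- function() {
  none <- factor(character(), levels = strength_levels, ordered = TRUE)
  tibble(
    drug = character(), event_pt = character(), a = integer(), b = integer(),
    c = integer(), d = integer(), n = integer(),
    prr = numeric(), prr_low = numeric(), prr_high = numeric(),
    prr_strength = none,
    ror = numeric(), ror_low = numeric(), ror_high = numeric(),
    ror_strength = none,
    chi2 = numeric(), mhra_prr = numeric(), mhra_strength = none,
    ic = numeric(), ic_sd = numeric(), ic_low = numeric(), ic_high = numeric(),
    bcpnn_strength = none, note = character()
  )
}

new_signal_screen <- function(x) {
  class(x) <- c("signal_screen", class(tibble()))
  x
}

#' Build a signal screen from pre-computed (printed) statistics
#'
#' Reporting-system denominators are often unpublished: a study may print
#' per-combination statistics (PRR/ROR with CIs, chi-square, IC with
#' interval) without the underlying 2x2 margins. This constructor accepts
#' such a table and produces a `signal_screen` usable for classification
#' and method comparison.
#'
#' @param stats A tibble with columns `drug`, `event_pt`, `cases`, `prr`,
#'   `prr_low`, `prr_high`, `ror`, `ror_low`, `ror_high`, `chi2`,
#'   `mhra_prr`, `ic`, `ic_low`, `ic_high`, and optionally the published
#'   determinations `prr_signal`, `ror_signal`, `mhra_signal` (logical)
#'   and `bcpnn_strength` (character/factor).
#' @param flags `"classified"` (default) derives every method's
#'   signal/strength by applying the standard rules to the printed
#'   statistics; `"printed"` takes the published determination columns
#'   as-is (strength columns for methods published only as yes/no are set
#'   to `weak` for flagged rows).
#' @return A `signal_screen` tibble (margins `b`, `c`, `d`, `n` are `NA`).
#' @export
screen_from_printed <- function(stats, flags = c("classified", "printed")) {
  flags <- match.arg(flags)
  out <- tibble(
    drug = stats$drug, event_pt = stats$event_pt,
    a = as.integer(stats$cases), b = NA_integer_, c = NA_integer_,
    d = NA_integer_, n = NA_integer_,
    prr = stats$prr, prr_low = stats$prr_low, prr_high = stats$prr_high,
    ror = stats$ror, ror_low = stats$ror_low, ror_high = stats$ror_high,
    chi2 = stats$chi2, mhra_prr = stats$mhra_prr,
    ic = stats$ic,
    ic_sd = (stats$ic - stats$ic_low) / 2,
    ic_low = stats$ic_low, ic_high = stats$ic_high,
    note = NA_character_
  )
  if (flags == "classified") {
    out$prr_strength <- classify_signal("PRR", lower = out$prr_low,
                                        n_cases = out$a)
    out$ror_strength <- classify_signal("ROR", lower = out$ror_low,
                                        n_cases = out$a)
    out$mhra_strength <- classify_signal("MHRA", chi2 = out$chi2,
                                         prr_point = out$mhra_prr,
                                         n_cases = out$a)
    out$bcpnn_strength <- classify_signal("BCPNN", lower = out$ic_low)
  } else {
    needed <- c("prr_signal", "ror_signal", "mhra_signal", "bcpnn_strength")
    missing <- setdiff(needed, names(stats))
    if (length(missing) > 0L) {
      abort(paste0("flags = \"printed\" requires columns: ",
                   paste(missing, collapse = ", ")))
    }
    yn <- function(x) {
      factor(ifelse(as_flag(x), "weak", "none"),
             levels = strength_levels, ordered = TRUE)
    }
    out$prr_strength <- yn(stats$prr_signal)
    out$ror_strength <- yn(stats$ror_signal)
    out$mhra_strength <- yn(stats$mhra_signal)
    out$bcpnn_strength <- factor(as.character(stats$bcpnn_strength),
                                 levels = strength_levels, ordered = TRUE)
  }
  out <- out %>% select(dplyr::all_of(names(empty_screen())))
  new_signal_screen(out)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("yes", "true", "1", "y")
}

#' Per-method signal flags of a screen
#'
#' @param screen A `signal_screen`.
#' @return A tibble `drug`, `event_pt`, `n_cases` plus one logical column
#'   per method (`PRR`, `ROR`, `MHRA`, `BCPNN`): strength above `none`.
#' @export
signal_flags <- function(screen) {
  tibble(
    drug = screen$drug, event_pt = screen$event_pt, n_cases = screen$a,
    PRR = screen$prr_strength != "none",
    ROR = screen$ror_strength != "none",
    MHRA = screen$mhra_strength != "none",
    BCPNN = screen$bcpnn_strength != "none"
  )
}
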