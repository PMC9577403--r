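# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized code paths.

# brute-force pair enumeration: explicit double loop over a report tibble
oracle_pair_count <- function(reports, drug_scope = NULL) {
  total <- 0L
  for (i in seq_len(nrow(reports))) {
    d <- reports$drugs[[i]]
    d <- d[d$drug_role %in% c("first_suspected", "suspected"), , drop = FALSE]
    if (!is.null(drug_scope)) {
      d <- d[d$drug_name %in% tolower(drug_scope), , drop = FALSE]
    }
    for (j in seq_len(nrow(d))) {
      for (k in seq_len(nrow(reports$events[[i]]))) total <- total + 1L
    }
  }
  total
}

# brute-force 2x2 quadruple count over an explicit pair list
oracle_table <- function(pairs, drug, event_pt) {
  a <- b <- c <- d <- 0L
  for (i in seq_len(nrow(pairs))) {
    isd <- tolower(pairs$drug[i]) == tolower(drug)
    ise <- tolower(pairs$event_pt[i]) == tolower(event_pt)
    if (isd && ise) a <- a + 1L
    else if (isd) b <- b + 1L
    else if (ise) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}

# hand-formula oracles on a single 2x2 table (no zero-cell handling)
oracle_prr <- function(a, b, c, d) {
  pt <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(point = pt, lower = exp(log(pt) - stats::qnorm(0.975) * se),
    upper = exp(log(pt) + stats::qnorm(0.975) * se))
}

oracle_ror <- function(a, b, c, d) {
  pt <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(point = pt, lower = exp(log(pt) - stats::qnorm(0.975) * se),
    upper = exp(log(pt) + stats::qnorm(0.975) * se))
}

oracle_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Monte-Carlo oracle for the BCPNN posterior: samples the model's
# posterior (three independent Betas) and summarises the IC draws
oracle_bcpnn_mc <- function(a, b, c, d, ndraw = 1e6) {
  C <- a + b + c + d
  cx <- a + b
  cy <- a + c
  g <- (C + 2)^2 / ((cx + 1) * (cy + 1))
  ic <- log2(rbeta(ndraw, a + 1, C - a + g - 1) /
               (rbeta(ndraw, cx + 1, C - cx + 1) *
                  rbeta(ndraw, cy + 1, C - cy + 1)))
  c(ic = mean(ic), sd = sd(ic))
}

# shoelace polygon area under a polyline closed through (1,0) and (0,0)
oracle_auc_shoelace <- function(x, y) {
  px <- c(x, 1, 0)
  py <- c(y, 0, 0)
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

# random non-degenerate 2x2 tables as a contingency tibble
random_tables <- function(n, a_rng = c(3, 40), b_rng = c(20, 300),
                          c_rng = c(5, 100), d_rng = c(500, 5000)) {
  tibble::tibble(
    drug = sprintf("drug%02d", seq_len(n)),
    event_pt = sprintf("event%02d", seq_len(n)),
    a = sample(a_rng[1]:a_rng[2], n, replace = TRUE),
    b = sample(b_rng[1]:b_rng[2], n, replace = TRUE),
    c = sample(c_rng[1]:c_rng[2], n, replace = TRUE),
    d = sample(d_rng[1]:d_rng[2], n, replace = TRUE)
  ) |> dplyr::mutate(n = a + b + c + d)
}

# compact constructor for a one-report row
make_report <- function(id, drugs, events, roles = "first_suspected",
                        serious = FALSE, certainty = "certain",
                        is_duplicate = FALSE, date = NA, age = NA_real_,
                        sex = "unknown") {
  tibble::tibble(
    report_id = id, report_date = as.Date(date), age_years = age, sex = sex,
    certainty = certainty, is_duplicate = is_duplicate,
    drugs = list(tibble::tibble(
      drug_name = drugs,
      drug_role = rep_len(roles, length(drugs))
    )),
    events = list(tibble::tibble(
      event_pt = events, event_soc = NA_character_,
      serious = rep_len(serious, length(events))
    ))
  )
}
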