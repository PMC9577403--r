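tbl1 <- function(a, b, c, d) {
  tibble::tibble(drug = "d", event_pt = "e", a = a, b = b, c = c, d = d,
                 n = a + b + c + d)
}

test_that("PRR point and interval match the hand formula", {
  expect_equal(prr(tbl1(5, 5, 5, 5))$point, 1.0)

  res <- prr(tbl1(10, 90, 10, 890))
  ora <- oracle_prr(10, 90, 10, 890)
  expect_equal(res$point, 9.0)
  expect_equal(res$lower, unname(ora["lower"]), tolerance = 1e-10)
  expect_equal(res$upper, unname(ora["upper"]), tolerance = 1e-10)
  expect_false(res$corrected)

  # exact agreement with the formula oracle on random tables
  set.seed(1)
  tabs <- random_tables(25)
  res <- prr(tabs)
  for (i in seq_len(nrow(tabs))) {
    ora <- oracle_prr(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$point[i], unname(ora["point"]))
    expect_equal(res$lower[i], unname(ora["lower"]))
  }
  # sign property: ad > bc implies PRR > 1
  up <- with(tabs, a * d > b * c)
  expect_true(all(res$point[up] > 1))
})

test_that("ROR matches the hand formula and dominates PRR above 1", {
  expect_equal(ror(tbl1(5, 5, 5, 5))$point, 1.0)
  expect_equal(round(ror(tbl1(10, 90, 10, 890))$point, 2), 9.89)
  set.seed(2)
  tabs <- random_tables(25)
  rr <- ror(tabs)
  pp <- prr(tabs)
  for (i in seq_len(nrow(tabs))) {
    ora <- oracle_ror(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(rr$point[i], unname(ora["point"]))
    expect_equal(rr$upper[i], unname(ora["upper"]))
  }
  above <- pp$point >= 1
  expect_true(all(rr$point[above] >= pp$point[above]))
})

test_that("zero cells trigger the continuity correction policy", {
  res <- prr(tbl1(4, 20, 0, 100))
  expect_true(res$corrected)
  expect_true(is.finite(res$lower) && res$lower > 0)
  res0 <- prr(tbl1(0, 20, 5, 100))
  expect_equal(res0$point, 0)
  expect_equal(res0$lower, 0)
  expect_equal(as.character(res0$strength), "none")
  expect_error(prr(tbl1(0, 0, 5, 100)), "degenerate margin")
})

test_that("MHRA chi-square matches the hand formula and the joint rule", {
  expect_equal(mhra(tbl1(10, 90, 90, 810))$point, 0) # ad = bc
  expect_equal(round(mhra(tbl1(10, 90, 10, 890))$point, 2), 36.28)
  set.seed(3)
  tabs <- random_tables(25)
  res <- mhra(tabs)
  for (i in seq_len(nrow(tabs))) {
    expect_equal(res$point[i],
                 oracle_chi2(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]))
  }
  # chi2 invariant under simultaneous row and column swap; nonnegative
  swapped <- tibble::tibble(drug = tabs$drug, event_pt = tabs$event_pt,
                            a = tabs$d, b = tabs$c, c = tabs$b, d = tabs$a,
                            n = tabs$n)
  expect_equal(mhra(swapped)$point, res$point)
  expect_true(all(res$point >= 0))
  # Yates correction shrinks chi2
  expect_true(all(mhra(tabs, yates = TRUE)$point <= res$point))
  expect_error(mhra(tbl1(0, 0, 5, 100)), "degenerate margin")
})

test_that("BCPNN IC vanishes under exact independence and shrinks", {
  n <- 10000
  expect_lt(abs(bcpnn(tbl1(n, n, n, n))$point), 0.001)
  set.seed(4)
  tabs <- random_tables(30, a_rng = c(1, 50))
  ic <- bcpnn(tabs)$point
  unshrunk <- with(tabs, log2(a * n / ((a + b) * (a + c))))
  expect_true(all(abs(ic) <= abs(unshrunk) + 1e-9))
  # shrinkage fades as cells grow with fixed proportions
  big <- tbl1(10 * 1e4, 90 * 1e4, 10 * 1e4, 890 * 1e4)
  expect_equal(bcpnn(big)$point,
               log2((10 / 1000) / ((100 / 1000) * (20 / 1000))),
               tolerance = 0.01)
})

test_that("exact BCPNN moments agree with posterior sampling; the classical
           closed form approaches them at large counts", {
  set.seed(5)
  tab <- tbl1(10, 90, 10, 890)
  ex <- bcpnn(tab, moments = "exact")
  mc <- oracle_bcpnn_mc(10, 90, 10, 890, ndraw = 5e5)
  expect_equal(ex$point, unname(mc["ic"]), tolerance = 0.01)
  expect_equal(ex$ic_sd, unname(mc["sd"]), tolerance = 0.01)
  # approximation error of the classical form is O(1/a)
  big <- tbl1(200, 1800, 200, 17800)
  expect_equal(bcpnn(big)$point, bcpnn(big, moments = "exact")$point,
               tolerance = 0.005)
})

test_that("sign coherence holds across all four statistics", {
  set.seed(6)
  tabs <- random_tables(40)
  s_prr <- sign(prr(tabs)$point - 1)
  s_ror <- sign(ror(tabs)$point - 1)
  s_det <- sign(with(tabs, a * d - b * c))
  s_ic0 <- sign(with(tabs, log2(a * n / ((a + b) * (a + c)))))
  nondeg <- s_det != 0
  expect_equal(s_prr[nondeg], s_det[nondeg])
  expect_equal(s_ror[nondeg], s_det[nondeg])
  expect_equal(s_ic0[nondeg], s_det[nondeg])
})

test_that("strength classification applies the published bands strictly", {
  # PRR: published determinations at the case floor
  expect_equal(as.character(classify_signal("PRR", lower = 1.39,
                                            n_cases = 57)), "weak")
  expect_equal(as.character(classify_signal("PRR", lower = 0.98,
                                            n_cases = 56)), "none")
  expect_equal(as.character(classify_signal("PRR", lower = 1.0,
                                            n_cases = 10)), "none")
  expect_equal(as.character(classify_signal("PRR", lower = 1.2,
                                            n_cases = 2)), "none")
  expect_equal(as.character(classify_signal("PRR", lower = 50,
                                            n_cases = 5)), "medium")
  expect_equal(as.character(classify_signal("PRR", lower = 1000,
                                            n_cases = 5)), "high")
  # MHRA: all three conditions, banded on chi2
  expect_equal(as.character(classify_signal("MHRA", chi2 = 40.31,
                                            prr_point = 20.69, n_cases = 4)),
               "weak")
  expect_equal(as.character(classify_signal("MHRA", chi2 = 19.11,
                                            prr_point = 1.78, n_cases = 57)),
               "none")
  expect_equal(as.character(classify_signal("MHRA", chi2 = 150,
                                            prr_point = 3, n_cases = 10)),
               "medium")
  # BCPNN: banded on IC - 2SD, boundaries inclusive on the upper side
  expect_equal(as.character(classify_signal("BCPNN", lower = 1.29)), "weak")
  expect_equal(as.character(classify_signal("BCPNN", lower = 0)), "none")
  expect_equal(as.character(classify_signal("BCPNN", lower = 1.5)), "weak")
  expect_equal(as.character(classify_signal("BCPNN", lower = 3.0)), "medium")
  expect_equal(as.character(classify_signal("BCPNN", lower = 3.01)), "high")
})

test_that("classification is monotone in the banded statistic", {
  lows <- sort(runif(50, 0, 1200))
  st <- classify_signal("PRR", lower = lows, n_cases = rep(10, 50))
  expect_true(all(diff(as.integer(st)) >= 0))
  chis <- sort(runif(50, 0, 1500))
  stm <- classify_signal("MHRA", chi2 = chis, prr_point = rep(5, 50),
                         n_cases = rep(10, 50))
  expect_true(all(diff(as.integer(stm)) >= 0))
})

test_that("detect_signals screens every combination and survives degenerate rows", {
  expect_equal(nrow(detect_signals(all_tables(fixture_pairs()[0, ]))), 0L)

  set.seed(8)
  pairs <- simulate_pairs(500, letters[1:3], LETTERS[1:4], seed = 8)
  screen <- detect_signals(all_tables(pairs, min_cases = 1L))
  expect_s3_class(screen, "signal_screen")
  expect_equal(nrow(screen),
               nrow(dplyr::distinct(pairs, drug, event_pt)))
  # a universe concentrated on one event makes c + d = 0 impossible to
  # avoid for that event: degenerate rows must be flagged, not fatal
  deg <- toy <- tibble::tibble(
    drug = c(rep("x", 4), rep("y", 3)),
    event_pt = "only", event_soc = NA, serious = FALSE,
    report_id = sprintf("r%d", 1:7)
  )
  sc <- detect_signals(all_tables(deg, min_cases = 1L))
  expect_true(all(!is.na(sc$note)))
  expect_true(all(is.na(sc$prr)))
  expect_true(all(is.finite(sc$ic)))
})

test_that("tidy and glance summarise a screen faithfully", {
  t5 <- load_fixture("printed_stats")
  screen <- screen_from_printed(t5)
  long <- tidy(screen)
  expect_equal(nrow(long), 4 * nrow(t5))
  expect_setequal(as.character(unique(long$method)),
                  c("PRR", "ROR", "MHRA", "BCPNN"))
  g <- glance(screen)
  expect_equal(g$n_combinations, 31L)
  expect_equal(g$prr_signals, 13L)
  expect_equal(g$ror_signals, 13L)
})
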