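write_listing <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("single-row listings and delimited cells parse as expected", {
  path <- write_listing(c(
    "report_id,drug_name,event_pt,sex,age_years",
    "r1,Levofloxacin,Rash,F,34"
  ))
  rep <- read_line_listing(path)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$drugs[[1]]$drug_name, "levofloxacin")
  expect_equal(rep$events[[1]]$event_pt, "rash")
  expect_equal(rep$sex, "female")
  expect_equal(rep$age_years, 34)

  path2 <- write_listing(c(
    "report_id,drug_name,event_pt",
    "r1,levofloxacin; ibuprofen,rash"
  ))
  rep2 <- read_line_listing(path2)
  expect_equal(nrow(rep2$drugs[[1]]), 2L)
  expect_equal(rep2$drugs[[1]]$drug_name, c("levofloxacin", "ibuprofen"))
})

test_that("column maps, missing columns and empty files behave per contract", {
  path <- write_listing(c("id,med,reaction", "r1,cipro,nausea"))
  rep <- read_line_listing(path, column_map = c(report_id = "id",
                                                drug_name = "med",
                                                event_pt = "reaction"))
  expect_equal(rep$report_id, "r1")
  expect_error(read_line_listing(path), "mandatory column")
  expect_error(
    read_line_listing(path, column_map = c(report_id = "nope")),
    "absent from the file"
  )
  empty <- write_listing("report_id,drug_name,event_pt")
  expect_warning(out <- read_line_listing(empty), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("malformed rows are rejected, not dropped, matching a row scan", {
  set.seed(41)
  n <- 20
  ids <- sprintf("r%02d", seq_len(n))
  drugs <- rep("levofloxacin", n)
  events <- rep("rash", n)
  bad <- sample(n, 3)
  drugs[bad[1]] <- ""
  events[bad[2]] <- ""
  ids[bad[3]] <- ""
  path <- write_listing(c("report_id,drug_name,event_pt",
                          paste(ids, drugs, events, sep = ",")))
  rep <- read_line_listing(path)
  # independent row-by-row scan of the same file
  raw <- utils::read.csv(path, colClasses = "character")
  ok <- vapply(seq_len(nrow(raw)), function(i) {
    all(nzchar(trimws(c(raw$report_id[i], raw$drug_name[i], raw$event_pt[i]))))
  }, logical(1))
  expect_equal(nrow(rep), sum(ok))
  expect_equal(nrow(rejected_rows(rep)), sum(!ok))
  expect_setequal(rejected_rows(rep)$reason,
                  c("missing report_id", "missing drug_name",
                    "missing event_pt"))
})

test_that("long-dialect rows sharing a report id merge into one report", {
  path <- write_listing(c(
    "report_id,drug_name,event_pt",
    "r1,levofloxacin,rash",
    "r1,levofloxacin,pruritus",
    "r2,moxifloxacin,nausea"
  ))
  rep <- read_line_listing(path)
  expect_equal(rep$report_id, c("r1", "r2"))
  expect_equal(nrow(rep$events[[1]]), 2L)
})

test_that("exclusion rules remove uncertain, duplicate and combination reports", {
  empty <- filter_reports(make_report("x", "d", "e")[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(exclusion_log(empty)), 0L)

  two <- dplyr::bind_rows(make_report("r1", "d", "e"),
                          make_report("r1", "d", "e2"))
  kept <- filter_reports(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(exclusion_log(kept)$reason, "duplicate")
  # first occurrence kept
  expect_equal(kept$events[[1]]$event_pt, "e")

  combo <- make_report("r9", c("d1", "d2"), "e",
                       roles = c("first_suspected", "suspected"))
  expect_equal(nrow(filter_reports(combo)), 1L)
  expect_equal(nrow(filter_reports(combo, exclude_combinations = TRUE)), 0L)
})

test_that("filtering matches a brute-force row filter on a synthetic set", {
  set.seed(42)
  reports <- dplyr::bind_rows(lapply(seq_len(50), function(i) {
    make_report(
      sprintf("r%02d", sample(45, 1)),  # some ids collide -> duplicates
      drugs = sample(letters[1:4], sample(1:2, 1)),
      events = "event",
      certainty = sample(c("certain", "probable", "uncertain"), 1,
                         prob = c(0.6, 0.2, 0.2)),
      is_duplicate = runif(1) < 0.1
    )
  }))
  kept <- filter_reports(reports, exclude_combinations = TRUE)
  # brute force: scan rows in order, applying all three rules
  seen <- character()
  keep <- logical(nrow(reports))
  for (i in seq_len(nrow(reports))) {
    r <- reports[i, ]
    keep[i] <- r$certainty != "uncertain" &&
      !r$is_duplicate && !(r$report_id %in% seen) &&
      sum(r$drugs[[1]]$drug_role %in% c("first_suspected", "suspected")) <= 1
    if (r$certainty != "uncertain" && !r$is_duplicate &&
          !(r$report_id %in% seen)) {
      seen <- c(seen, r$report_id)
    }
  }
  expect_equal(nrow(kept), sum(keep))
  expect_equal(nrow(kept) + nrow(exclusion_log(kept)), nrow(reports))
})

test_that("fuzzy duplicate mode matches on clinical content", {
  a <- make_report("idA", "levofloxacin", c("rash", "pruritus"),
                   date = "2020-01-02", age = 60, sex = "male")
  b <- make_report("idB", "levofloxacin", c("pruritus", "rash"),
                   date = "2020-01-02", age = 60, sex = "male")
  both <- dplyr::bind_rows(a, b)
  expect_equal(nrow(filter_reports(both)), 2L)
  expect_equal(nrow(filter_reports(both, fuzzy_duplicates = TRUE)), 1L)
})

test_that("pair expansion is the cartesian product and honours scope", {
  r <- make_report("r1", c("d1", "d2"), c("e1", "e2", "e3"),
                   roles = "suspected")
  expect_equal(nrow(expand_pairs(r)), 6L)
  expect_equal(nrow(expand_pairs(r, drug_scope = "D1")), 3L)

  set.seed(7)
  reports <- dplyr::bind_rows(lapply(seq_len(30), function(i) {
    make_report(sprintf("s%02d", i),
                drugs = sample(letters[1:5], sample(1:3, 1)),
                events = sample(LETTERS[1:6], sample(1:3, 1)))
  }))
  pairs <- expand_pairs(reports)
  expect_equal(nrow(pairs), oracle_pair_count(reports))
  scope <- c("a", "b")
  expect_equal(nrow(expand_pairs(reports, drug_scope = scope)),
               oracle_pair_count(reports, drug_scope = scope))
  # determinism and order preservation
  expect_identical(pairs, expand_pairs(reports))
  expect_equal(unique(pairs$report_id), reports$report_id)
})

test_that("canonical listing round-trips field-equal", {
  reports <- dplyr::bind_rows(
    make_report("r1", c("levofloxacin", "aspirin"), c("rash", "nausea"),
                roles = c("first_suspected", "concomitant"),
                serious = c(TRUE, FALSE), age = 71, sex = "female",
                date = "2019-06-30", certainty = "probable"),
    make_report("r2", "moxifloxacin", "phlebitis")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_line_listing(reports, path)
  back <- read_line_listing(path)
  attr(back, "rejects") <- NULL
  attr(reports, "rejects") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(reports))
})
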