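#' Read a spontaneous-report line listing
#'
#' Reads an ADR (adverse drug reaction) line listing from a delimited text
#' file or spreadsheet and assembles one validated report per `report_id`.
#' Both dialects commonly exported by reporting systems are accepted: *long*
#' (one row per report-drug-event record, rows sharing a `report_id` are
#' merged into one report) and *wide* (one row per report, with multi-valued
#' drug/event cells separated by `delim`). The two may be mixed freely.
#'
#' Mandatory fields are `report_id`, `drug_name` and `event_pt` (the MedDRA
#' preferred term). Rows in which any of these cannot be parsed are not
#' silently dropped: they are collected into a rejects table available via
#' [rejected_rows()]. A file lacking a mandatory *column* altogether is a
#' configuration error.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"csv"`, or `"xlsx"`.
#' @param column_map Optional named character vector mapping canonical names
#'   (`report_id`, `report_date`, `age_years`, `sex`, `drug_name`,
#'   `drug_role`, `event_pt`, `event_soc`, `serious`, `certainty`,
#'   `is_duplicate`) to the column names used in the file. Canonical names
#'   already present in the file need not be mapped.
#' @param delim Delimiter separating values inside multi-valued drug/event
#'   cells (default `";"`). Surrounding whitespace is stripped.
#' @return A tibble with one row per report: `report_id`, `report_date`
#'   (`Date`, `NA` when absent or unparseable), `age_years`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `certainty` (`"certain"`,
#'   `"probable"`, `"possible"`, `"uncertain"`), `is_duplicate`, and two
#'   list-columns: `drugs` (tibbles with `drug_name`, `drug_role`) and
#'   `events` (tibbles with `event_pt`, `event_soc`, `serious`). The rejects
#'   table is attached as attribute `"rejects"`.
#' @seealso [filter_reports()], [expand_pairs()], [write_line_listing()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "report_id,drug_name,event_pt",
#'   "r1,levofloxacin;ibuprofen,rash"
#' ), path)
#' read_line_listing(path)
read_line_listing <- function(path, format = c("auto", "csv", "xlsx"),
                              column_map = NULL, delim = ";") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading xlsx files requires the 'readxl' package")
    }
    readxl::read_excel(path, col_types = "text")
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  raw <- as_tibble(raw)
  if (nrow(raw) == 0L) {
    warn(paste0("empty line listing: ", path))
    return(empty_reports())
  }

  # apply column map: canonical name <- file column
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0L) {
      abort(paste0("column_map refers to columns absent from the file: ",
                   paste(missing_src, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  mandatory <- c("report_id", "drug_name", "event_pt")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0L) {
    abort(paste0("mandatory column missing from line listing: ",
                 paste(absent, collapse = ", ")))
  }
  for (col in setdiff(canonical_columns, names(raw))) raw[[col]] <- NA_character_

  assemble_reports(raw, delim = delim)
}

empty_reports <- function() {
  out <- tibble(
    report_id = character(), report_date = as.Date(character()),
    age_years = numeric(), sex = character(), certainty = character(),
    is_duplicate = logical(), drugs = list(), events = list()
  )
  attr(out, "rejects") <- tibble(row = integer(), report_id = character(),
                                 reason = character())
  out
}

split_cell <- function(x, delim) {
  if (is.na(x)) return(character())
  parts <- trimws(strsplit(x, delim, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

normalize_sex <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  dplyr::case_when(
    x %in% c("m", "male", "1") ~ "male",
    x %in% c("f", "female", "2") ~ "female",
    TRUE ~ "unknown"
  )
}

normalize_certainty <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  # unstated certainty is treated as "possible": only explicit "uncertain"
  # should trigger exclusion downstream
  dplyr::case_when(
    x %in% c("certain", "definite") ~ "certain",
    x %in% c("probable", "likely") ~ "probable",
    x %in% c("uncertain", "unlikely", "doubtful") ~ "uncertain",
    TRUE ~ "possible"
  )
}

normalize_role <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  dplyr::case_when(
    x %in% c("first_suspected", "first suspected", "primary suspect", "ps", "1") ~ "first_suspected",
    x %in% c("concomitant", "c") ~ "concomitant",
    TRUE ~ "suspected"
  )
}

parse_logical <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  x %in% c("true", "t", "yes", "y", "1", "serious")
}

# Build nested reports from a raw character tibble holding all canonical
# columns; rows failing mandatory-field parsing go to the rejects table.
assemble_reports <- function(raw, delim) {
  n <- nrow(raw)
  rid <- trimws(ifelse(is.na(raw$report_id), "", raw$report_id))
  drugs_split <- lapply(raw$drug_name, split_cell, delim = delim)
  events_split <- lapply(raw$event_pt, split_cell, delim = delim)

  reason <- rep(NA_character_, n)
  reason[!nzchar(rid)] <- "missing report_id"
  reason[is.na(reason) & lengths(drugs_split) == 0L] <- "missing drug_name"
  reason[is.na(reason) & lengths(events_split) == 0L] <- "missing event_pt"

  rejects <- tibble(row = which(!is.na(reason)),
                    report_id = rid[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  keep <- which(is.na(reason))

  age <- suppressWarnings(as.numeric(raw$age_years))
  age[!is.na(age) & (age < 0 | age > 130)] <- NA_real_
  date <- suppressWarnings(as.Date(raw$report_date, format = "%Y-%m-%d"))

  recycle <- function(vals, k, default) {
    if (length(vals) == 0L) rep(default, k)
    else if (length(vals) == k) vals
    else rep(vals[1], k)
  }

  rows <- lapply(keep, function(i) {
    dn <- drugs_split[[i]]
    dr <- normalize_role(recycle(split_cell(raw$drug_role[i], delim),
                                 length(dn), "suspected"))
    ep <- events_split[[i]]
    es <- recycle(split_cell(raw$event_soc[i], delim), length(ep), NA_character_)
    ser <- parse_logical(recycle(split_cell(raw$serious[i], delim),
                                 length(ep), "no"))
    tibble(
      report_id = rid[i], report_date = date[i], age_years = age[i],
      sex = normalize_sex(raw$sex[i]),
      certainty = normalize_certainty(raw$certainty[i]),
      is_duplicate = parse_logical(raw$is_duplicate[i]),
      drugs = list(tibble(drug_name = tolower(dn), drug_role = dr)),
      events = list(tibble(event_pt = tolower(ep), event_soc = es, serious = ser))
    )
  })
  out <- if (length(rows) == 0L) empty_reports() else bind_rows(rows)

  # merge rows sharing a report_id (long dialect) into single reports
  if (nrow(out) > 0L && anyDuplicated(out$report_id)) {
    out <- out %>%
      group_by(.data$report_id) %>%
      summarise(
        report_date = dplyr::first(.data$report_date),
        age_years = dplyr::first(.data$age_years),
        sex = dplyr::first(.data$sex),
        certainty = dplyr::first(.data$certainty),
        is_duplicate = any(.data$is_duplicate),
        drugs = list(distinct(bind_rows(.data$drugs))),
        events = list(distinct(bind_rows(.data$events))),
        .groups = "drop"
      ) %>%
      # preserve first-appearance order of report ids
      arrange(match(.data$report_id, unique(rid)))
  }
  attr(out, "rejects") <- rejects
  out
}

#' Rows rejected while reading a line listing
#'
#' @param reports A reports tibble returned by [read_line_listing()].
#' @return A tibble with columns `row`, `report_id`, `reason`.
#' @export
rejected_rows <- function(reports) {
  attr(reports, "rejects") %||% tibble(row = integer(), report_id = character(),
                                       reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the standard report exclusion rules
#'
#' Removes reports that pharmacovigilance practice excludes before
#' disproportionality analysis: reports whose causality assessment is
#' `uncertain`, duplicate reports, and (optionally) drug-combination reports
#' listing more than one suspected drug. Every removed report is logged with
#' exactly one reason; the log is attached as attribute `"exclusions"` and
#' retrievable via [exclusion_log()].
#'
#' Duplicate detection keys on `report_id` by default (first occurrence
#' kept, `is_duplicate` flags honoured). An optional fuzzy mode additionally
#' matches reports agreeing on date, age, sex, the sorted drug set and the
#' sorted event set.
#'
#' @param reports A reports tibble (see [read_line_listing()]).
#' @param exclude_combinations Remove reports with more than one drug in a
#'   suspected role (`first_suspected` or `suspected`)? Default `FALSE`:
#'   combination reports are common and the suspected-drug role is usually
#'   the better scoping device.
#' @param fuzzy_duplicates Also match duplicates on clinical content
#'   (date + age + sex + sorted drugs + sorted events)? Default `FALSE`.
#' @return The retained reports, with the exclusion log (tibble
#'   `report_id`, `reason`) attached as attribute `"exclusions"`.
#' @export
filter_reports <- function(reports, exclude_combinations = FALSE,
                           fuzzy_duplicates = FALSE) {
  if (nrow(reports) == 0L) {
    attr(reports, "exclusions") <- tibble(report_id = character(),
                                          reason = character())
    return(reports)
  }
  reason <- rep(NA_character_, nrow(reports))

  reason[reports$certainty == "uncertain"] <- "uncertain"

  dup <- reports$is_duplicate | duplicated(reports$report_id)
  if (fuzzy_duplicates) {
    key <- vapply(seq_len(nrow(reports)), function(i) {
      paste(
        as.character(reports$report_date[i]), reports$age_years[i],
        reports$sex[i],
        paste(sort(reports$drugs[[i]]$drug_name), collapse = "|"),
        paste(sort(reports$events[[i]]$event_pt), collapse = "|"),
        sep = "#"
      )
    }, character(1))
    dup <- dup | duplicated(key)
  }
  reason[is.na(reason) & dup] <- "duplicate"

  if (exclude_combinations) {
    n_susp <- vapply(reports$drugs, function(d) {
      sum(d$drug_role %in% c("first_suspected", "suspected"))
    }, integer(1))
    reason[is.na(reason) & n_susp > 1L] <- "drug_combination"
  }

  keep <- is.na(reason)
  out <- reports[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble(report_id = reports$report_id[!keep],
                                    reason = reason[!keep])
  attr(out, "rejects") <- attr(reports, "rejects")
  out
}

#' Exclusion log of a filtered report set
#'
#' @param reports A reports tibble returned by [filter_reports()].
#' @return A tibble with columns `report_id` and `reason` (one of
#'   `"uncertain"`, `"duplicate"`, `"drug_combination"`).
#' @export
exclusion_log <- function(reports) {
  attr(reports, "exclusions") %||% tibble(report_id = character(),
                                          reason = character())
}

#' Expand reports into drug-event pairs
#'
#' The atomic unit of disproportionality analysis is the drug-event pair:
#' each report contributes the cartesian product of its drugs and its
#' events. A report listing 2 drugs and 3 events therefore contributes 6
#' pairs. When `drug_scope` is given only drugs in scope are expanded
#' (matching is case-insensitive).
#'
#' @param reports A validated reports tibble.
#' @param drug_scope Optional character vector of generic drug names.
#' @param suspected_only Restrict to drugs in a suspected role
#'   (`first_suspected`/`suspected`)? Default `TRUE` — concomitant
#'   medication is not normally attributed the event.
#' @return A tibble with one row per (report, drug, event) triple:
#'   `drug`, `event_pt`, `event_soc`, `serious`, `report_id`, in input
#'   order.
#' @export
expand_pairs <- function(reports, drug_scope = NULL, suspected_only = TRUE) {
  if (nrow(reports) == 0L) {
    return(tibble(drug = character(), event_pt = character(),
                  event_soc = character(), serious = logical(),
                  report_id = character()))
  }
  scope <- if (!is.null(drug_scope)) tolower(trimws(drug_scope))
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    d <- reports$drugs[[i]]
    if (suspected_only) {
      d <- d[d$drug_role %in% c("first_suspected", "suspected"), , drop = FALSE]
    }
    if (!is.null(scope)) d <- d[d$drug_name %in% scope, , drop = FALSE]
    e <- reports$events[[i]]
    if (nrow(d) == 0L || nrow(e) == 0L) return(NULL)
    tidyr::crossing(drug = d$drug_name, idx = seq_len(nrow(e))) %>%
      mutate(event_pt = e$event_pt[.data$idx],
             event_soc = e$event_soc[.data$idx],
             serious = e$serious[.data$idx],
             report_id = reports$report_id[i]) %>%
      select("drug", "event_pt", "event_soc", "serious", "report_id")
  })
  bind_rows(rows)
}

#' Write reports to the canonical line-listing CSV
#'
#' One row per (report, drug, event) record, using the canonical column
#' names accepted by [read_line_listing()]; re-reading the file yields
#' field-equal reports.
#'
#' @param reports A reports tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(reports, path) {
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    d <- reports$drugs[[i]]
    e <- reports$events[[i]]
    tidyr::crossing(di = seq_len(nrow(d)), ei = seq_len(nrow(e))) %>%
      mutate(
        report_id = reports$report_id[i],
        report_date = as.character(reports$report_date[i]),
        age_years = reports$age_years[i],
        sex = reports$sex[i],
        drug_name = d$drug_name[.data$di],
        drug_role = d$drug_role[.data$di],
        event_pt = e$event_pt[.data$ei],
        event_soc = e$event_soc[.data$ei],
        serious = e$serious[.data$ei],
        certainty = reports$certainty[i],
        is_duplicate = reports$is_duplicate[i]
      ) %>%
      select(dplyr::all_of(canonical_columns))
  })
  out <- if (length(rows) == 0L) {
    as_tibble(setNames(rep(list(character()), length(canonical_columns)),
                       canonical_columns))
  } else {
    bind_rows(rows)
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a drug-event pair table to CSV
#'
#' @param pairs A pair tibble from [expand_pairs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_csv(pairs, path, na = "", progress = FALSE)
  invisible(path)
}
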