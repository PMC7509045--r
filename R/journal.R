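# Treatment-journal and census input: parsing, validation, and the
# inclusion filters (entry lag, study window, continuous recording,
# plausibility caps).

.journal_csv_cols <- c("event_id", "farm_id", "age_category", "substance",
                       "amount_mg", "n_animals", "n_days",
                       "application_date", "entry_date")

.census_csv_cols <- c("farm_id", "age_category", "animals_per_year",
                      "continuous_recording")

new_journal <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("amu_journal", "data.frame")
  df
}

#' Construct a single treatment record
#'
#' One journal entry: a group of animals of one age category treated with
#' one product (possibly a combination of several active agents) for a
#' number of consecutive days. `substances` is a named numeric vector:
#' names are substance identifiers, values the total amount of that active
#' substance administered over the whole event, in mg.
#'
#' @param farm_id Farm identifier.
#' @param age_category One of the five age categories ([age_categories()]).
#' @param substances Named numeric vector of per-substance amounts (mg),
#'   all positive.
#' @param n_animals Number of animals treated (>= 1).
#' @param n_days Number of treatment days (>= 1).
#' @param application_date,entry_date Dates; `entry_date` must not precede
#'   `application_date`.
#' @return A list of class `treatment_record`.
#' @examples
#' treatment_record("F1", "weaned_piglet", c(amoxicillin = 5000), 20, 3)
#' @export
treatment_record <- function(farm_id, age_category, substances,
                             n_animals, n_days,
                             application_date = as.Date("2019-01-15"),
                             entry_date = application_date) {
  age_category <- .check_category(age_category)
  if (!is.numeric(substances) || !length(substances) ||
      is.null(names(substances)) || any(!nzchar(names(substances)))) {
    abort_validation("substances must be a non-empty named numeric vector of mg amounts")
  }
  names(substances) <- norm_substance(names(substances))
  if (anyDuplicated(names(substances))) {
    abort_validation("duplicate substance within one treatment record")
  }
  if (any(!is.finite(substances) | substances <= 0)) {
    abort_validation("every substance amount must be > 0 mg")
  }
  if (!is_count(n_animals)) abort_validation("n_animals must be a positive count")
  if (!is_count(n_days)) abort_validation("n_days must be a positive count")
  application_date <- as.Date(application_date)
  entry_date <- as.Date(entry_date)
  if (is.na(application_date) || is.na(entry_date)) {
    abort_validation("dates must be valid")
  }
  if (entry_date < application_date) {
    abort_validation("entry_date must not precede application_date")
  }
  structure(list(farm_id = as.character(farm_id),
                 age_category = age_category,
                 substances = substances,
                 n_animals = as.integer(n_animals),
                 n_days = as.integer(n_days),
                 application_date = application_date,
                 entry_date = entry_date),
            class = "treatment_record")
}

#' Build a validated journal from a data frame
#'
#' A journal holds one row per (event, substance); rows sharing an
#' `event_id` describe a combination product and must agree on farm,
#' category, group size, duration and dates. Row-level problems are
#' collected and reported together in a single parse error (rows are never
#' silently dropped).
#'
#' @param x Data frame with the journal CSV columns (see [read_journal()]).
#' @return An object of class `amu_journal` (a data frame).
#' @export
journal <- function(x) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.journal_csv_cols, names(x))
  if (length(miss)) {
    abort_schema(sprintf("journal is missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  df <- x[.journal_csv_cols]
  df$event_id <- as.character(df$event_id)
  df$farm_id <- as.character(df$farm_id)
  df$age_category <- as.character(df$age_category)
  df$substance <- norm_substance(df$substance)
  df$amount_mg <- suppressWarnings(as.numeric(df$amount_mg))
  df$n_animals <- suppressWarnings(as.numeric(df$n_animals))
  df$n_days <- suppressWarnings(as.numeric(df$n_days))
  app <- parse_iso_date(df$application_date)
  ent <- parse_iso_date(df$entry_date)

  errs <- character(0)
  bad_row <- function(i, why) sprintf("row %d: %s", i, why)
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$event_id[i])) errs <- c(errs, bad_row(i, "empty event_id"))
    if (!df$age_category[i] %in% .age_category_table$name) {
      errs <- c(errs, bad_row(i, sprintf("unknown age_category '%s'", df$age_category[i])))
    }
    if (!nzchar(df$substance[i])) errs <- c(errs, bad_row(i, "empty substance"))
    if (!is.finite(df$amount_mg[i]) || df$amount_mg[i] <= 0) {
      errs <- c(errs, bad_row(i, "amount_mg must be > 0"))
    }
    if (!isTRUE(is_count(df$n_animals[i]))) {
      errs <- c(errs, bad_row(i, "n_animals must be a positive count"))
    }
    if (!isTRUE(is_count(df$n_days[i]))) {
      errs <- c(errs, bad_row(i, "n_days must be a positive count"))
    }
    if (is.na(app[i])) errs <- c(errs, bad_row(i, "malformed application_date (ISO-8601 expected)"))
    if (is.na(ent[i])) errs <- c(errs, bad_row(i, "malformed entry_date (ISO-8601 expected)"))
    if (!is.na(app[i]) && !is.na(ent[i]) && ent[i] < app[i]) {
      errs <- c(errs, bad_row(i, "entry_date precedes application_date"))
    }
  }
  if (length(errs)) {
    abort_parse(sprintf("journal has %d invalid row(s):\n%s",
                        length(errs), paste(errs, collapse = "\n")))
  }
  df$application_date <- app
  df$entry_date <- ent
  df$n_animals <- as.integer(df$n_animals)
  df$n_days <- as.integer(df$n_days)

  # per-event consistency (combination products as multiple substance rows)
  ev_errs <- character(0)
  for (id in unique(df$event_id)) {
    rows <- df[df$event_id == id, ]
    if (nrow(rows) == 1) next
    same <- function(col) length(unique(rows[[col]])) == 1
    if (!all(vapply(c("farm_id", "age_category", "n_animals", "n_days"),
                    same, logical(1))) ||
        length(unique(as.numeric(rows$application_date))) != 1 ||
        length(unique(as.numeric(rows$entry_date))) != 1) {
      ev_errs <- c(ev_errs, sprintf("event %s: inconsistent fields across substance rows", id))
    }
    if (anyDuplicated(rows$substance)) {
      ev_errs <- c(ev_errs, sprintf("event %s: duplicate substance", id))
    }
  }
  if (length(ev_errs)) {
    abort_parse(sprintf("journal has inconsistent event(s):\n%s",
                        paste(ev_errs, collapse = "\n")))
  }
  new_journal(df)
}

#' Read a treatment journal from CSV
#'
#' Expected header:
#' `event_id,farm_id,age_category,substance,amount_mg,n_animals,n_days,application_date,entry_date`.
#' Rows sharing an `event_id` (combination products) are merged into one
#' logical record with several substances.
#'
#' @param path Path to the journal CSV.
#' @return An `amu_journal`.
#' @export
read_journal <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("journal file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), .journal_csv_cols)) {
    abort_schema(sprintf("journal header must be exactly: %s",
                         paste(.journal_csv_cols, collapse = ",")))
  }
  journal(df)
}

#' Extract the list of treatment records from a journal
#'
#' @param j An `amu_journal`.
#' @return A list of [treatment_record()] objects, one per event, in order
#'   of first appearance.
#' @export
journal_records <- function(j) {
  stopifnot(inherits(j, "amu_journal"))
  ids <- unique(j$event_id)
  lapply(ids, function(id) {
    rows <- j[j$event_id == id, ]
    treatment_record(rows$farm_id[1], rows$age_category[1],
                     setNames(rows$amount_mg, rows$substance),
                     rows$n_animals[1], rows$n_days[1],
                     rows$application_date[1], rows$entry_date[1])
  })
}

#' Convert a list of treatment records into a journal
#'
#' @param records List of [treatment_record()] objects.
#' @param event_id Optional character vector of event identifiers (default
#'   `"E1"`, `"E2"`, ...).
#' @return An `amu_journal`.
#' @export
as_journal <- function(records, event_id = NULL) {
  if (inherits(records, "treatment_record")) records <- list(records)
  event_id <- event_id %||% sprintf("E%d", seq_along(records))
  parts <- Map(function(r, id) {
    data.frame(event_id = id, farm_id = r$farm_id,
               age_category = r$age_category,
               substance = names(r$substances),
               amount_mg = unname(r$substances),
               n_animals = r$n_animals, n_days = r$n_days,
               application_date = format(r$application_date, "%Y-%m-%d"),
               entry_date = format(r$entry_date, "%Y-%m-%d"),
               stringsAsFactors = FALSE)
  }, records, event_id)
  journal(do.call(rbind, parts))
}

# ---- validation report ------------------------------------------------

validation_report <- function(n_input, rejected) {
  rejected <- rejected %||% data.frame(index = integer(0),
                                       event_id = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)
  out <- list(n_input = as.integer(n_input),
              n_kept = as.integer(n_input - nrow(rejected)),
              rejected = rejected)
  stopifnot(out$n_input == out$n_kept + nrow(out$rejected))
  class(out) <- "amu_validation_report"
  out
}

#' @export
print.amu_validation_report <- function(x, ...) {
  cat(sprintf("validation report: %d event(s) in, %d kept, %d rejected\n",
              x$n_input, x$n_kept, nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

# shared event-level filter: keep_fun(ev) returns NA (keep) or a reason
.filter_events <- function(j, reason_fun) {
  stopifnot(inherits(j, "amu_journal"))
  ids <- unique(j$event_id)
  ev <- j[!duplicated(j$event_id), ]
  reasons <- reason_fun(ev, j)
  stopifnot(length(reasons) == length(ids))
  rej <- which(!is.na(reasons))
  rejected <- data.frame(index = rej, event_id = ids[rej],
                         reason = reasons[rej], stringsAsFactors = FALSE)
  kept <- new_journal(j[j$event_id %in% ids[is.na(reasons)], , drop = FALSE])
  list(journal = kept, report = validation_report(length(ids), rejected))
}

#' Entry-lag inclusion filter
#'
#' Records must be entered in the electronic journal no later than
#' `max_lag_days` after application (default 7, the programme requirement).
#' Later entries are rejected with reason `"entry_lag"`.
#'
#' @param j An `amu_journal`.
#' @param max_lag_days Maximum allowed entry lag in days.
#' @return A list with elements `journal` (kept events, order preserved)
#'   and `report` (an `amu_validation_report`).
#' @export
apply_entry_lag_filter <- function(j, max_lag_days = 7) {
  .filter_events(j, function(ev, full) {
    lag <- as.numeric(ev$entry_date - ev$application_date)
    ifelse(lag > max_lag_days, "entry_lag", NA_character_)
  })
}

#' Study-window filter
#'
#' Events applied outside `[start, end]` are rejected with reason
#' `"out_of_window"`. Default window: 2018-10-01 to 2019-09-30.
#'
#' @param j An `amu_journal`.
#' @param start,end Window bounds (inclusive), `Date` or ISO strings.
#' @return As [apply_entry_lag_filter()].
#' @export
apply_window_filter <- function(j, start = as.Date("2018-10-01"),
                                end = as.Date("2019-09-30")) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    abort_domain("invalid study window")
  }
  .filter_events(j, function(ev, full) {
    ifelse(ev$application_date < start | ev$application_date > end,
           "out_of_window", NA_character_)
  })
}

#' Continuous-recording filter
#'
#' Operationalizes the "recorded continuously for the study period"
#' inclusion rule: an event is kept only if the census has an entry for its
#' (farm, age category) pair (`"no_census"` otherwise) with the
#' `continuous_recording` flag set (`"not_continuous"` otherwise). Journal
#' sparsity alone cannot distinguish low usage from non-recording, so the
#' census flag is the source of truth.
#'
#' @param j An `amu_journal`.
#' @param census An `amu_census` (see [read_census()]).
#' @return As [apply_entry_lag_filter()].
#' @export
apply_continuity_filter <- function(j, census) {
  stopifnot(inherits(census, "amu_census"))
  key <- function(f, c) paste(f, c, sep = "\r")
  ck <- key(census$farm_id, census$age_category)
  cont <- setNames(census$continuous_recording, ck)
  .filter_events(j, function(ev, full) {
    k <- key(ev$farm_id, ev$age_category)
    ifelse(!k %in% ck, "no_census",
           ifelse(!cont[k], "not_continuous", NA_character_))
  })
}

#' Plausibility caps
#'
#' Numeric caps for the removal of records "clearly identified as
#' incorrect". The source analysis does not quantify its caps; the defaults
#' here are deliberately loose so that only entry errors are caught:
#' at most 20,000 animals per event, at most 365 treatment days, and an
#' implied per-animal-day dose of at most `max_dose_multiple` (default 10)
#' times the catalog dose at standard weight.
#'
#' @param max_animals,max_days,max_dose_multiple Positive caps.
#' @return A list of class `plausibility_rules`.
#' @export
plausibility_rules <- function(max_animals = 20000, max_days = 365,
                               max_dose_multiple = 10) {
  stopifnot(max_animals >= 1, max_days >= 1, max_dose_multiple > 0)
  structure(list(max_animals = max_animals, max_days = max_days,
                 max_dose_multiple = max_dose_multiple),
            class = "plausibility_rules")
}

#' Plausibility filter
#'
#' Rejects events violating any cap of [plausibility_rules()], with reasons
#' `"animals"`, `"duration"` or `"dose"`. The dose rule compares the
#' implied per-kg-per-day dose, `amount_mg / (n_animals * n_days * SW)`,
#' against `max_dose_multiple * ddd` and needs the catalog; events with a
#' substance absent from the catalog are rejected with reason
#' `"unknown_substance"` rather than crashing. When several caps are
#' violated the first in the order animals, duration, unknown_substance,
#' dose is reported.
#'
#' @param j An `amu_journal`.
#' @param rules A [plausibility_rules()].
#' @param catalog A [ddd_catalog()], required for the dose rule; pass
#'   `NULL` to skip it.
#' @return As [apply_entry_lag_filter()].
#' @export
apply_plausibility_filter <- function(j, rules = plausibility_rules(),
                                      catalog = NULL) {
  stopifnot(inherits(rules, "plausibility_rules"))
  .filter_events(j, function(ev, full) {
    reasons <- rep(NA_character_, nrow(ev))
    reasons[ev$n_animals > rules$max_animals] <- "animals"
    over_days <- is.na(reasons) & ev$n_days > rules$max_days
    reasons[over_days] <- "duration"
    if (!is.null(catalog)) {
      idx <- match(full$substance, catalog$substance)
      sw <- standard_weight(full$age_category)
      implied <- full$amount_mg / (full$n_animals * full$n_days * sw)
      unknown <- tapply(is.na(idx), full$event_id, any)[ev$event_id]
      over <- !is.na(idx) &
        implied > rules$max_dose_multiple * catalog$ddd_mg_per_kg[idx]
      over_ev <- tapply(over, full$event_id, any)[ev$event_id]
      reasons[is.na(reasons) & unknown] <- "unknown_substance"
      reasons[is.na(reasons) & over_ev] <- "dose"
    }
    reasons
  })
}

# ---- census -----------------------------------------------------------

#' Construct a farm census
#'
#' The indicator denominator: animals housed (sows) or produced (growing
#' categories) per farm and year, plus the continuous-recording flag used
#' by [apply_continuity_filter()].
#'
#' @param x Data frame with columns `farm_id`, `age_category`,
#'   `animals_per_year` and (optionally) `continuous_recording`.
#' @return An object of class `amu_census`.
#' @export
farm_census <- function(x) {
  stopifnot(is.data.frame(x))
  need <- .census_csv_cols[1:3]
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_schema(sprintf("census is missing columns: %s",
                         paste(miss, collapse = ", ")))
  }
  df <- data.frame(farm_id = as.character(x$farm_id),
                   age_category = .check_category(x$age_category),
                   animals_per_year = suppressWarnings(as.numeric(x$animals_per_year)),
                   stringsAsFactors = FALSE)
  df$continuous_recording <- if ("continuous_recording" %in% names(x)) {
    v <- x$continuous_recording
    if (is.character(v)) v <- tolower(trimws(v)) %in% c("true", "t", "1", "yes")
    as.logical(v)
  } else TRUE
  bad <- !is.finite(df$animals_per_year) | df$animals_per_year < 1
  if (any(bad)) {
    abort_validation(sprintf("animals_per_year must be >= 1 (farm %s)",
                             paste(unique(df$farm_id[bad]), collapse = ", ")))
  }
  key <- paste(df$farm_id, df$age_category)
  if (anyDuplicated(key)) {
    abort_validation(sprintf("duplicate (farm, age_category) in census: %s",
                             paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  rownames(df) <- NULL
  class(df) <- c("amu_census", "data.frame")
  df
}

#' Read a farm census from CSV
#'
#' Expected header:
#' `farm_id,age_category,animals_per_year,continuous_recording`
#' (last column true/false).
#'
#' @param path Path to the census CSV.
#' @return An `amu_census`.
#' @export
read_census <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("census file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), .census_csv_cols)) {
    abort_schema(sprintf("census header must be exactly: %s",
                         paste(.census_csv_cols, collapse = ",")))
  }
  farm_census(df)
}
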