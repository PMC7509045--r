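test_that("journal parsing merges combination products and keeps events", {
  j <- journal(fix_journal_df())
  expect_s3_class(j, "amu_journal")
  recs <- journal_records(j)
  expect_length(recs, 3)               # E2 has two substance rows, one event
  e2 <- recs[[2]]
  expect_length(e2$substances, 2)
  expect_equal(sort(names(e2$substances)), c("sulfadimidine", "trimethoprim"))

  # one event per row -> one record per row
  df <- fix_journal_df()[c(1, 4), ]
  expect_length(journal_records(journal(df)), 2)
})

test_that("row-level problems are collected into a parse error", {
  df <- fix_journal_df()
  df$n_animals[1] <- 0
  expect_error(journal(df), "row 1", class = "amu_parse_error")

  df <- fix_journal_df()
  df$amount_mg[2] <- -5
  df$application_date[4] <- "10.01.2019"
  err <- tryCatch(journal(df), error = identity)
  expect_s3_class(err, "amu_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "row 4")

  df <- fix_journal_df()
  df$entry_date[1] <- "2019-01-01"     # before application
  expect_error(journal(df), class = "amu_parse_error")

  # inconsistent fields across substance rows of one event
  df <- fix_journal_df()
  df$n_animals[3] <- 99
  expect_error(journal(df), "E2", class = "amu_parse_error")
})

test_that("journal CSV schema is enforced", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(fix_journal_df(), path, row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_journal(path)), 4)
  write.csv(fix_journal_df()[, -1], path, row.names = FALSE)
  expect_error(read_journal(path), class = "amu_schema_error")
})

test_that("entry-lag filter keeps lag 7, rejects lag 8, handles empty input", {
  df <- fix_journal_df()[c(1, 4), ]
  df$application_date <- "2019-01-01"
  df$entry_date <- c("2019-01-08", "2019-01-09")   # lags 7 and 8
  res <- apply_entry_lag_filter(journal(df))
  expect_equal(res$report$n_input, 2)
  expect_equal(res$report$n_kept, 1)
  expect_equal(res$journal$event_id, "E1")
  expect_equal(res$report$rejected$reason, "entry_lag")
  expect_equal(res$report$rejected$event_id, "E3")

  empty <- journal(fix_journal_df()[0, ])
  res0 <- apply_entry_lag_filter(empty)
  expect_equal(res0$report$n_input, 0)
  expect_equal(nrow(res0$journal), 0)
})

test_that("window filter rejects out-of-window applications", {
  df <- fix_journal_df()[c(1, 4), ]
  df$application_date <- c("2018-09-30", "2018-10-01")
  df$entry_date <- df$application_date
  res <- apply_window_filter(journal(df))
  expect_equal(res$report$rejected$reason, "out_of_window")
  expect_equal(res$journal$event_id, "E3")
})

test_that("continuity filter uses the census flag", {
  cen <- farm_census(data.frame(
    farm_id = c("F1", "F2"), age_category = c("weaned_piglet", "fattening_pig"),
    animals_per_year = c(2000, 1050),
    continuous_recording = c(TRUE, FALSE)))
  j <- journal(fix_journal_df())
  res <- apply_continuity_filter(j, cen)
  expect_equal(res$report$n_kept, 2)   # F1 weaned events kept
  expect_equal(sort(res$report$rejected$reason), "not_continuous")

  cen2 <- farm_census(data.frame(farm_id = "F1", age_category = "weaned_piglet",
                                 animals_per_year = 2000,
                                 continuous_recording = TRUE))
  res2 <- apply_continuity_filter(j, cen2)
  expect_true("no_census" %in% res2$report$rejected$reason)
})

test_that("plausibility filter applies caps with specific reasons", {
  cat <- fix_catalog()
  mk <- function(n_animals = 20, n_days = 3, amount = NULL, sub = "amoxicillin",
                 category = "weaned_piglet") {
    # default: dosed exactly at ddd x SW per animal-day
    ddd <- cat$ddd_mg_per_kg[match(sub, cat$substance)]
    amount <- amount %||% (ddd * standard_weight(category) * n_animals * n_days)
    as_journal(list(treatment_record("F1", category,
                                     setNames(amount, sub), n_animals, n_days)))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  # exactly at SPC dose with M = 10 -> kept
  res <- apply_plausibility_filter(mk(), plausibility_rules(), cat)
  expect_equal(res$report$n_kept, 1)

  # duration cap
  res <- apply_plausibility_filter(mk(n_days = 400),
                                   plausibility_rules(max_days = 365), cat)
  expect_equal(res$report$rejected$reason, "duration")

  # animals cap
  res <- apply_plausibility_filter(mk(n_animals = 30000),
                                   plausibility_rules(), cat)
  expect_equal(res$report$rejected$reason, "animals")

  # dose cap: 20 x ddd x SW with M = 10 -> rejected
  # implied per-day dose = amount / (n_animals * n_days * SW) = 20 * ddd
  amount20 <- 20 * 20 * 12 * 20 * 3
  res <- apply_plausibility_filter(mk(amount = amount20),
                                   plausibility_rules(max_dose_multiple = 10),
                                   cat)
  expect_equal(res$report$rejected$reason, "dose")

  # unknown substance under the dose rule -> rejection, not a crash
  res <- apply_plausibility_filter(mk(sub = "mystery", amount = 100),
                                   plausibility_rules(), cat)
  expect_equal(res$report$rejected$reason, "unknown_substance")
})

test_that("validation reports always reconcile and filters compose/commute", {
  set.seed(11)
  # records each violating at most one rule
  n <- 40
  recs <- lapply(seq_len(n), function(i) {
    lag <- if (i %% 5 == 0) 9 else sample(0:7, 1)         # some lag violations
    days <- if (i %% 7 == 0) 400 else sample(1:10, 1)     # some duration ones
    app <- as.Date("2019-01-01") + i
    treatment_record("F1", "weaned_piglet", c(amoxicillin = 240 * 5 * days),
                     5, days, app, app + lag)
  })
  j <- as_journal(recs)
  rules <- plausibility_rules(max_days = 365)
  cat <- fix_catalog()

  a <- apply_entry_lag_filter(j)
  ab <- apply_plausibility_filter(a$journal, rules, cat)
  b <- apply_plausibility_filter(j, rules, cat)
  ba <- apply_entry_lag_filter(b$journal)

  expect_setequal(ab$journal$event_id, ba$journal$event_id)
  expect_lte(nrow(ab$journal), nrow(j))
  for (rep in list(a$report, ab$report, b$report, ba$report)) {
    expect_equal(rep$n_input, rep$n_kept + nrow(rep$rejected))
  }
})

test_that("census validation catches duplicates and non-positive counts", {
  expect_s3_class(fix_census(), "amu_census")
  expect_error(farm_census(data.frame(
    farm_id = c("F1", "F1"), age_category = c("weaned_piglet", "weaned_piglet"),
    animals_per_year = c(2000, 1000), continuous_recording = TRUE)),
    class = "amu_validation_error")
  expect_error(farm_census(data.frame(
    farm_id = "F1", age_category = "weaned_piglet",
    animals_per_year = 0, continuous_recording = TRUE)),
    class = "amu_validation_error")
  # magnitudes straight from the published medians parse fine
  cen <- farm_census(data.frame(
    farm_id = c("F1", "F1", "F2"),
    age_category = c("weaned_piglet", "fattening_pig", "lactating_sow"),
    animals_per_year = c(2000, 1050, 22), continuous_recording = TRUE))
  expect_equal(nrow(cen), 3)
})
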