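test_that("treatment counting follows the one-application-per-animal-per-day rule", {
  r1 <- treatment_record("F1", "weaned_piglet", c(amoxicillin = 5000), 20, 3)
  expect_equal(count_treatments(r1), 60)   # 20 animals x 3 days

  r2 <- treatment_record("F1", "weaned_piglet",
                         c(trimethoprim = 960, sulfadimidine = 4800), 10, 2)
  expect_equal(count_treatments(r2), 40)   # each agent counted separately

  r3 <- treatment_record("F1", "weaned_piglet", c(amoxicillin = 240), 1, 1)
  expect_equal(count_treatments(r3), 1)
})

test_that("long-acting multiplier scales treatment days only when opted in", {
  cat <- fix_catalog()                      # doxycycline laf 1, sulfadimidine 2
  r <- treatment_record("F1", "weaned_piglet", c(sulfadimidine = 4800), 10, 2)
  expect_equal(count_treatments(r), 20)
  expect_equal(count_treatments(r, cat, use_long_acting = TRUE), 40)
  expect_error(count_treatments(r, use_long_acting = TRUE),
               class = "amu_domain_error")
})

test_that("dose counting divides amount by ddd x standard weight", {
  cat <- ddd_catalog("amoxicillin", 10, "penicillins")
  r <- treatment_record("F1", "weaned_piglet", c(amoxicillin = 5000), 20, 3)
  expect_equal(unname(count_nddd(r, cat)), 5000 / (10 * 12))

  # dosed exactly per SPC at standard weight -> nDDD = NT per substance
  for (category in age_categories()$name) {
    sw <- standard_weight(category)
    r <- treatment_record("F1", category, c(amoxicillin = 10 * sw * 7 * 4), 7, 4)
    expect_equal(unname(count_nddd(r, cat)), 7 * 4)
  }

  r_bad <- treatment_record("F1", "weaned_piglet", c(unknown = 100), 2, 2)
  err <- tryCatch(count_nddd(r_bad, cat), error = identity)
  expect_s3_class(err, "amu_validation_error")
  expect_match(conditionMessage(err), "unknown")
})

test_that("aggregation sums records and divides by the census denominator", {
  j <- journal(fix_journal_df()[1:3, ])    # E1 (60 NT) + E2 (40 NT), farm F1
  cen <- fix_census()
  tab <- aggregate_indicators(j, cen, fix_catalog())
  tot <- tab[tab$farm_id == "F1" & tab$age_category == "weaned_piglet" &
               tab$substance_class == "TOTAL", ]
  expect_equal(tot$nt, 100)
  expect_equal(tot$ati, 100 / 2000)

  # class rows sum to the TOTAL row
  f1 <- tab[tab$farm_id == "F1" & tab$substance_class != "TOTAL", ]
  expect_equal(sum(f1$nt), tot$nt)
  expect_equal(sum(f1$nddd), tot$nddd)

  # censused pairs without records get explicit zero TOTAL rows
  z <- tab[tab$farm_id == "F2" & tab$age_category == "weaned_piglet", ]
  expect_equal(z$substance_class, "TOTAL")
  expect_equal(z$nt, 0)
  expect_equal(z$nddd_per_animal_year, 0)

  # denominator contract: ati * denominator = nt
  den <- attr(tab, "denominators")
  d <- den$denominator[match(paste(tab$farm_id, tab$age_category),
                             paste(den$farm_id, den$age_category))]
  expect_equal(tab$ati * d, tab$nt)
})

test_that("aggregation errors on missing denominators, naming the pairs", {
  j <- journal(fix_journal_df())
  cen <- farm_census(data.frame(farm_id = "F1", age_category = "weaned_piglet",
                                animals_per_year = 2000,
                                continuous_recording = TRUE))
  err <- tryCatch(aggregate_indicators(j, cen, fix_catalog()),
                  error = identity)
  expect_s3_class(err, "amu_validation_error")
  expect_match(conditionMessage(err), "F2")
})

test_that("additivity: aggregating concatenated journals sums row-wise", {
  set.seed(3)
  cat <- fix_catalog()
  mk_recs <- function(k, farm) {
    lapply(seq_len(k), function(i) {
      sub <- sample(cat$substance, 1)
      treatment_record(farm, sample(age_categories()$name, 1),
                       setNames(runif(1, 100, 9000), sub),
                       sample(1:50, 1), sample(1:10, 1))
    })
  }
  r1 <- mk_recs(12, "F1"); r2 <- mk_recs(9, "F2")
  cen <- farm_census(expand.grid(farm_id = c("F1", "F2"),
                                 age_category = age_categories()$name,
                                 stringsAsFactors = FALSE) |>
                       transform(animals_per_year = 1000,
                                 continuous_recording = TRUE))
  j1 <- as_journal(r1, sprintf("A%d", seq_along(r1)))
  j2 <- as_journal(r2, sprintf("B%d", seq_along(r2)))
  j12 <- journal(rbind(as.data.frame(j1), as.data.frame(j2)))
  t1 <- aggregate_indicators(j1, cen, cat)
  t2 <- aggregate_indicators(j2, cen, cat)
  t12 <- aggregate_indicators(j12, cen, cat)
  key <- function(t) paste(t$farm_id, t$age_category, t$substance_class)
  added <- setNames(rep(0, length(unique(c(key(t1), key(t2))))),
                    unique(c(key(t1), key(t2))))
  for (t in list(t1, t2)) added[key(t)] <- added[key(t)] + t$nt
  expect_equal(unname(added[key(t12)]), t12$nt)
})

test_that("nddd is invariant to rescaling amounts and ddd together", {
  j <- journal(fix_journal_df())
  cen <- fix_census()
  cat1 <- fix_catalog()
  cat2 <- cat1; cat2$ddd_mg_per_kg <- cat1$ddd_mg_per_kg * 7.3
  j2 <- as.data.frame(j)
  j2$amount_mg <- j2$amount_mg * 7.3
  j2$application_date <- format(j2$application_date)
  j2$entry_date <- format(j2$entry_date)
  t1 <- aggregate_indicators(j, cen, cat1)
  t2 <- aggregate_indicators(journal(j2), cen, cat2)
  expect_equal(t2$nddd, t1$nddd)
  expect_equal(t2$nt, t1$nt)
})

test_that("identity limit: SPC dosing at standard weight gives nt == nddd", {
  set.seed(5)
  cat <- fix_catalog()
  recs <- lapply(1:20, function(i) {
    sub <- sample(cat$substance, 1)
    ddd <- cat$ddd_mg_per_kg[match(sub, cat$substance)]
    category <- sample(age_categories()$name, 1)
    n <- sample(1:40, 1); d <- sample(1:10, 1)
    treatment_record("F1", category,
                     setNames(ddd * standard_weight(category) * n * d, sub),
                     n, d)
  })
  cen <- farm_census(data.frame(farm_id = "F1",
                                age_category = age_categories()$name,
                                animals_per_year = 500,
                                continuous_recording = TRUE))
  tab <- aggregate_indicators(as_journal(recs), cen, cat)
  expect_equal(tab$nddd, tab$nt, tolerance = 1e-9)
  expect_equal(tab$ati, tab$nddd_per_animal_year, tolerance = 1e-9)
})

test_that("indicator table CSV round-trips with deterministic order", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- aggregate_indicators(journal(fix_journal_df()), fix_census(),
                              fix_catalog())
  write_indicator_table(tab, path)
  back <- read_indicator_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE, tolerance = 1e-12)
})
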