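# Seeded synthetic-data generator: farms, censuses and treatment journals
# with the statistical structure the analysis assumes. The central
# mechanism is the multiplicative dose deviation: changing the
# administered dose changes the number of defined daily doses but not the
# number of treatments, which is exactly what makes the two indicators
# diverge.

# standing-herd turnover per year, used to bound treated group sizes for
# "produced" categories (annual production >> animals present at a time)
.turnover <- c(suckling_piglet = 10, weaned_piglet = 8, fattening_pig = 3,
               lactating_sow = 1, gestating_sow = 1)

.farm_type_categories <- list(
  fattening = "fattening_pig",
  breeding = c("lactating_sow", "gestating_sow", "suckling_piglet",
               "weaned_piglet"),
  farrow_finish = c("lactating_sow", "gestating_sow", "suckling_piglet",
                    "weaned_piglet", "fattening_pig")
  # sow_pool farms draw one of two variants at generation time
)

.expand_by_substance <- function(x, substances, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(substances)), substances))
  }
  if (is.null(names(x))) abort_validation(sprintf("%s must be a scalar or named by substance", what))
  out <- setNames(rep(NA_real_, length(substances)), substances)
  nm <- norm_substance(names(x))
  unknown <- setdiff(nm, substances)
  if (length(unknown)) {
    abort_validation(sprintf("%s names not in catalog: %s", what,
                             paste(unknown, collapse = ", ")))
  }
  out[nm] <- as.numeric(x)
  out[is.na(out)] <- if (what == "dose_bias") 1 else 0
  out
}

# derive a per-farm seed from the global seed; a counter-based split so
# adding farms does not perturb existing farms' draws
.farm_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 69621 + i * 30011) %% 2147483629)
}

.day_prob <- function(max_days) {
  p <- 0.75^(seq_len(max_days) - 1)
  p / sum(p)
}

#' Simulation configuration
#'
#' The stated world of the generator. Defaults emulate the monitoring
#' programme the analysis was built for: 880 farms split into 399
#' fattening, 14 plain breeding, 190 sow-pool-affiliated and 277
#' farrow-to-finish farms; log-normal herd sizes centred on the published
#' per-category medians (2,200 suckling / 2,000 weaned / 1,050 fattening
#' pigs produced, 22 lactating / 75 gestating sows housed); negative-
#' binomial therapy-event counts per farm-year; and multiplicative
#' log-normal deviations of the administered dose and the true treated
#' weight from the catalog dose and the standard weight.
#'
#' `dose_sigma` is the key dial of the divergence mechanism: at 0 every
#' event is dosed exactly per catalog at standard weight and the two
#' indicators coincide identically; the larger it gets the further
#' nDDDch drifts from NT while NT is untouched.
#'
#' @param n_fattening,n_breeding,n_sow_pool,n_farrow_finish Farm counts
#'   per type (>= 0, at least one farm in total).
#' @param herd_median Named numeric, median animals per year per category.
#' @param herd_sigma Log-sd of the log-normal herd-size distribution.
#' @param event_rate_mean Named numeric, mean therapy events per farm-year
#'   per category.
#' @param event_rate_dispersion Negative-binomial size parameter.
#' @param group_frac_shape Beta shape pair for the treated fraction of the
#'   standing herd.
#' @param max_days Maximum treatment duration (days, default 14).
#' @param substance_weights Optional named sampling weights over catalog
#'   substances (default uniform).
#' @param combo_prob Probability that an event uses the two-agent
#'   combination product (trimethoprim/sulfonamide), if present in the
#'   catalog.
#' @param dose_sigma Log-sd of the multiplicative dose deviation; scalar
#'   or named per substance.
#' @param dose_bias Systematic multiplicative dose bias; scalar or named
#'   per substance (default 1).
#' @param weight_sigma Log-sd of the deviation of true treated weight from
#'   the standard weight.
#' @param error_rate Fraction of events corrupted for filter testing
#'   (amount x 100, or entry lag beyond 7 days).
#' @param window_start,window_end Study window (defaults 2018-10-01 to
#'   2019-09-30).
#' @param catalog A [ddd_catalog()]; default [amu_example_catalog()].
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `amu_sim_config`.
#' @export
sim_config <- function(n_fattening = 399L, n_breeding = 14L,
                       n_sow_pool = 190L, n_farrow_finish = 277L,
                       herd_median = c(suckling_piglet = 2200,
                                       weaned_piglet = 2000,
                                       fattening_pig = 1050,
                                       lactating_sow = 22,
                                       gestating_sow = 75),
                       herd_sigma = 0.8,
                       event_rate_mean = c(suckling_piglet = 4,
                                           weaned_piglet = 5,
                                           fattening_pig = 4,
                                           lactating_sow = 6,
                                           gestating_sow = 4),
                       event_rate_dispersion = 1.2,
                       group_frac_shape = c(1.2, 6),
                       max_days = 14L,
                       substance_weights = NULL,
                       combo_prob = 0.1,
                       dose_sigma = 0.3,
                       dose_bias = 1,
                       weight_sigma = 0.2,
                       error_rate = 0,
                       window_start = as.Date("2018-10-01"),
                       window_end = as.Date("2019-09-30"),
                       catalog = NULL,
                       seed = 1L) {
  counts <- c(n_fattening, n_breeding, n_sow_pool, n_farrow_finish)
  if (any(!is.finite(counts) | counts < 0 | counts != floor(counts))) {
    abort_validation("farm-type counts must be non-negative integers")
  }
  if (sum(counts) < 1) abort_validation("need at least one farm")
  cats <- .age_category_table$name
  if (!all(cats %in% names(herd_median)) || any(herd_median[cats] < 1)) {
    abort_validation("herd_median must name all five categories with values >= 1")
  }
  if (!all(cats %in% names(event_rate_mean)) || any(event_rate_mean[cats] < 0)) {
    abort_validation("event_rate_mean must name all five categories, values >= 0")
  }
  if (herd_sigma < 0 || weight_sigma < 0 || any(dose_sigma < 0)) {
    abort_validation("sigmas must be >= 0")
  }
  if (event_rate_dispersion <= 0) abort_validation("event_rate_dispersion must be > 0")
  if (length(group_frac_shape) != 2 || any(group_frac_shape <= 0)) {
    abort_validation("group_frac_shape must be two positive shapes")
  }
  if (combo_prob < 0 || combo_prob > 1) abort_validation("combo_prob must be in [0, 1]")
  if (error_rate < 0 || error_rate >= 1) abort_validation("error_rate must be in [0, 1)")
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end) || window_end < window_start) {
    abort_validation("invalid study window")
  }
  if (!is_count(max_days)) abort_validation("max_days must be a positive count")
  structure(list(n_fattening = as.integer(n_fattening),
                 n_breeding = as.integer(n_breeding),
                 n_sow_pool = as.integer(n_sow_pool),
                 n_farrow_finish = as.integer(n_farrow_finish),
                 herd_median = herd_median[cats], herd_sigma = herd_sigma,
                 event_rate_mean = event_rate_mean[cats],
                 event_rate_dispersion = event_rate_dispersion,
                 group_frac_shape = group_frac_shape,
                 max_days = as.integer(max_days),
                 substance_weights = substance_weights,
                 combo_prob = combo_prob,
                 dose_sigma = dose_sigma, dose_bias = dose_bias,
                 weight_sigma = weight_sigma, error_rate = error_rate,
                 window_start = window_start, window_end = window_end,
                 catalog = catalog, seed = as.integer(seed)),
            class = "amu_sim_config")
}

.combo_pair <- function(catalog) {
  tmp <- catalog$substance[catalog$substance_class == "trimethoprim"]
  sul <- catalog$substance[catalog$substance_class == "sulfonamides"]
  if (length(tmp) && length(sul)) c(tmp[1], sul[1]) else NULL
}

#' Generate a synthetic journal, census and truth set
#'
#' Deterministic given `config$seed`: a fixed global seed is split into
#' one counter-based stream per farm, so changing the number of farms does
#' not perturb earlier farms' draws, and changing `dose_sigma` alone
#' changes only the dose deviations (the event structure -- farms, events,
#' group sizes, durations, substances, dates -- is drawn from the same
#' stream positions regardless).
#'
#' Each therapy event draws: substance(s), a treated group bounded by the
#' standing herd, a duration of 1..`max_days` days, a true treated weight
#' `SW * exp(weight_sigma * z_w)`, and per substance a dose multiplier
#' `dose_bias * exp(dose_sigma * z)`. The administered amount is then
#' `ddd * multiplier * true_weight * n_animals * n_days` mg. A configured
#' fraction of events is corrupted (amount x 100, or entry lag 8..30 days)
#' for the validation filters to catch.
#'
#' @param config A [sim_config()].
#' @return A list of class `amu_simulation`: `journal` (an `amu_journal`),
#'   `census` (an `amu_census`), `catalog`, `truth` (list with `records`
#'   -- per event-substance true amounts, multipliers and corruption flags
#'   -- and `indicators` -- exact per-farm NT/nDDDch implied by the clean
#'   events), and `config`.
#' @export
simulate_amu <- function(config = sim_config()) {
  stopifnot(inherits(config, "amu_sim_config"))
  catalog <- config$catalog %||% amu_example_catalog()
  stopifnot(inherits(catalog, "ddd_catalog"))
  subs <- catalog$substance
  w <- if (is.null(config$substance_weights)) {
    setNames(rep(1, length(subs)), subs)
  } else {
    .expand_by_substance(config$substance_weights, subs, "substance_weights")
  }
  sig <- .expand_by_substance(config$dose_sigma, subs, "dose_sigma")
  bias <- .expand_by_substance(config$dose_bias, subs, "dose_bias")
  ddd <- setNames(catalog$ddd_mg_per_kg, subs)
  cls <- setNames(catalog$substance_class, subs)
  combo <- .combo_pair(catalog)
  window_len <- as.integer(config$window_end - config$window_start) + 1L

  types <- rep(c("fattening", "breeding", "sow_pool", "farrow_finish"),
               c(config$n_fattening, config$n_breeding,
                 config$n_sow_pool, config$n_farrow_finish))
  n_farm <- length(types)
  farm_ids <- sprintf("F%04d", seq_len(n_farm))

  jl <- list(); cl <- list(); tl <- list()
  for (i in seq_len(n_farm)) {
    set.seed(.farm_seed(config$seed, i))
    cats <- if (types[i] == "sow_pool") {
      if (runif(1) < 0.5) c("lactating_sow", "suckling_piglet", "weaned_piglet")
      else "gestating_sow"
    } else .farm_type_categories[[types[i]]]

    for (cat in cats) {
      herd <- max(1L, as.integer(round(
        rlnorm(1, log(config$herd_median[[cat]]), config$herd_sigma))))
      cl[[length(cl) + 1L]] <- data.frame(
        farm_id = farm_ids[i], age_category = cat,
        animals_per_year = herd, continuous_recording = TRUE,
        stringsAsFactors = FALSE)
      n_ev <- rnbinom(1, size = config$event_rate_dispersion,
                      mu = config$event_rate_mean[[cat]])
      if (n_ev == 0) next

      standing <- max(1L, as.integer(ceiling(herd / .turnover[[cat]])))
      sub1 <- sample(subs, n_ev, replace = TRUE, prob = w)
      is_combo <- runif(n_ev) < config$combo_prob & !is.null(combo)
      days <- sample.int(config$max_days, n_ev, replace = TRUE,
                         prob = .day_prob(config$max_days))
      frac <- rbeta(n_ev, config$group_frac_shape[1], config$group_frac_shape[2])
      grp <- pmax(1L, pmin(standing, as.integer(round(frac * standing))))
      zw <- rnorm(n_ev)
      app <- config$window_start + (sample.int(window_len, n_ev, replace = TRUE) - 1L)
      lag <- sample(0:7, n_ev, replace = TRUE)
      z1 <- rnorm(n_ev)
      z2 <- rnorm(n_ev)
      u_err <- runif(n_ev)
      u_typ <- runif(n_ev)

      s1 <- ifelse(is_combo, combo[1], sub1)
      wdev <- exp(config$weight_sigma * zw)
      sw <- standard_weight(cat)
      corrupted <- u_err < config$error_rate
      amt_fac <- ifelse(corrupted & u_typ < 0.5, 100, 1)
      lag_out <- ifelse(corrupted & u_typ >= 0.5,
                        8L + as.integer(floor((u_typ - 0.5) * 2 * 23)), lag)
      ev_id <- sprintf("%s-%s-%04d", farm_ids[i], cat, seq_len(n_ev))

      build_rows <- function(sub, z, keep) {
        mult <- bias[sub] * exp(sig[sub] * z)             # dose multiplier
        true_amt <- ddd[sub] * mult * sw * wdev * grp * days
        data.frame(event_id = ev_id, farm_id = farm_ids[i],
                   age_category = cat, substance = sub,
                   amount_mg = true_amt * amt_fac,
                   n_animals = grp, n_days = days,
                   application_date = format(app, "%Y-%m-%d"),
                   entry_date = format(app + lag_out, "%Y-%m-%d"),
                   true_amount_mg = true_amt,
                   dose_multiplier = unname(mult),
                   weight_multiplier = wdev,
                   corrupted = corrupted,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
      }
      rows <- rbind(build_rows(s1, z1, rep(TRUE, n_ev)),
                    build_rows(rep(combo[2] %||% subs[1], n_ev), z2, is_combo))
      jl[[length(jl) + 1L]] <- rows[c(.journal_csv_cols)]
      tl[[length(tl) + 1L]] <- rows[c("event_id", "farm_id", "age_category",
                                      "substance", "n_animals", "n_days",
                                      "true_amount_mg", "dose_multiplier",
                                      "weight_multiplier", "corrupted")]
    }
  }

  census <- farm_census(do.call(rbind, cl))
  jdf <- if (length(jl)) do.call(rbind, jl) else {
    setNames(data.frame(matrix(character(0), 0, length(.journal_csv_cols)),
                        stringsAsFactors = FALSE), .journal_csv_cols)
  }
  truth_rec <- if (length(tl)) do.call(rbind, tl) else NULL
  if (!is.null(truth_rec)) {
    truth_rec$substance_class <- unname(cls[truth_rec$substance])
  }
  truth <- list(records = truth_rec,
                indicators = .truth_indicators(truth_rec, census, ddd, cls))
  structure(list(journal = journal(jdf), census = census, catalog = catalog,
                 truth = truth, config = config),
            class = "amu_simulation")
}

# exact NT / nDDDch bookkeeping implied by the generated events, computed
# from the generative multipliers (an algebraic route independent of the
# pipeline's amount / (ddd * SW) division)
.truth_indicators <- function(rec, census, ddd, cls, keep_events = NULL) {
  if (!is.null(rec)) {
    keep <- if (is.null(keep_events)) !rec$corrupted else rec$event_id %in% keep_events
    rec <- rec[keep, , drop = FALSE]
  }
  key <- function(f, c, s) paste(f, c, s, sep = "\r")
  if (!is.null(rec) && nrow(rec)) {
    nt <- rec$n_animals * rec$n_days
    nddd <- rec$dose_multiplier * rec$weight_multiplier * nt
    k_cls <- key(rec$farm_id, rec$age_category, unname(cls[rec$substance]))
    k_tot <- key(rec$farm_id, rec$age_category, "TOTAL")
    nt_s <- tapply(c(nt, nt), c(k_cls, k_tot), sum)
    nddd_s <- tapply(c(nddd, nddd), c(k_cls, k_tot), sum)
  } else {
    nt_s <- nddd_s <- setNames(numeric(0), character(0))
  }
  zero_k <- setdiff(key(census$farm_id, census$age_category, "TOTAL"),
                    names(nt_s))
  keys <- c(names(nt_s), zero_k)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(farm_id = parts[, 1], age_category = parts[, 2],
                    substance_class = parts[, 3],
                    nt = c(as.numeric(nt_s), rep(0, length(zero_k))),
                    nddd = c(as.numeric(nddd_s), rep(0, length(zero_k))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$farm_id, out$age_category, out$substance_class), ]
  rownames(out) <- NULL
  out
}

#' Check pipeline recovery of the simulated truth
#'
#' Compares an indicator table computed by the pipeline against the exact
#' NT/nDDDch values implied by the generated events. With a clean run
#' (error rate 0, no filtering losses) the two must agree to floating-point
#' round-off on every (farm, category, class) key; with corrupted records
#' removed by the filters, pass the kept event ids and recovery must hold
#' on the kept subset's truth.
#'
#' @param table An `amu_indicator_table` from [aggregate_indicators()].
#' @param sim An `amu_simulation`.
#' @param kept_event_ids Optional character vector of events that survived
#'   filtering; default: all uncorrupted events.
#' @param tol Maximum tolerated relative error (default 1e-9).
#' @return A list of class `amu_recovery`: `ok`, `n_compared`,
#'   `max_rel_err_nt`, `max_rel_err_nddd`, `n_key_mismatch`.
#' @export
truth_check <- function(table, sim, kept_event_ids = NULL, tol = 1e-9) {
  stopifnot(inherits(table, "amu_indicator_table"),
            inherits(sim, "amu_simulation"))
  cls <- setNames(sim$catalog$substance_class, sim$catalog$substance)
  ddd <- setNames(sim$catalog$ddd_mg_per_kg, sim$catalog$substance)
  truth <- .truth_indicators(sim$truth$records, sim$census, ddd, cls,
                             keep_events = kept_event_ids)
  key <- function(d) paste(d$farm_id, d$age_category, d$substance_class,
                           sep = "\r")
  tk <- key(table); rk <- key(truth)
  shared <- intersect(tk, rk)
  n_mismatch <- length(setdiff(tk, rk)) + length(setdiff(rk, tk))
  ti <- match(shared, tk); ri <- match(shared, rk)
  rel <- function(a, b) {
    e <- abs(a - b) / pmax(abs(b), 1)
    e[a == b] <- 0
    e
  }
  err_nt <- rel(table$nt[ti], truth$nt[ri])
  err_nddd <- rel(table$nddd[ti], truth$nddd[ri])
  out <- list(ok = n_mismatch == 0 && length(shared) > 0 &&
                max(err_nt, err_nddd) <= tol,
              n_compared = length(shared),
              max_rel_err_nt = if (length(shared)) max(err_nt) else NA_real_,
              max_rel_err_nddd = if (length(shared)) max(err_nddd) else NA_real_,
              n_key_mismatch = n_mismatch)
  class(out) <- "amu_recovery"
  out
}

#' @export
print.amu_recovery <- function(x, ...) {
  cat(sprintf(
    "truth recovery: %s (%d keys, max rel err nt %.3g / nddd %.3g, %d key mismatches)\n",
    if (x$ok) "ok" else "FAILED", x$n_compared,
    x$max_rel_err_nt, x$max_rel_err_nddd, x$n_key_mismatch))
  invisible(x)
}

#' Write a simulation to CSV files
#'
#' Writes `journal.csv`, `census.csv`, `catalog.csv` (the exact pipeline
#' input schemas) and `truth.csv` into a directory.
#'
#' @param sim An `amu_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "amu_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- as.data.frame(sim$journal)
  j$application_date <- format(j$application_date, "%Y-%m-%d")
  j$entry_date <- format(j$entry_date, "%Y-%m-%d")
  write.csv(j, file.path(dir, "journal.csv"), row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(sim$census), file.path(dir, "census.csv"),
            row.names = FALSE, quote = FALSE)
  write_ddd_catalog(sim$catalog, file.path(dir, "catalog.csv"))
  write.csv(sim$truth$records, file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(dir)
}
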