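# Orchestration: distribution summaries, the end-to-end pipeline, and a
# small command-line driver.

#' Summarize indicator distributions across farms
#'
#' For every (age category, substance class) present in the table and each
#' of the four indicators (NT, ATI, nDDDch, nDDDch/animal/year): the total
#' over farms, min, the 10/25/50/75/90 percentiles, max and the sample
#' standard deviation (n-1; reported as 0 for a single farm). Class rows
#' summarize the farms that used the class; `TOTAL` rows cover all
#' censused farms including zero-usage ones.
#'
#' @param table An `amu_indicator_table`.
#' @param method Percentile method: `"linear"` (interpolation between
#'   order statistics, quantile type 7, the common statistical-software
#'   default) or `"nearest"` (nearest-rank, type 1).
#' @return A data frame of class `amu_summary_table` with columns
#'   `age_category, substance_class, indicator, n_farms, total, min, p10,
#'   p25, median, p75, p90, max, sd`.
#' @export
summarize_indicators <- function(table, method = c("linear", "nearest")) {
  stopifnot(inherits(table, "amu_indicator_table"))
  if (!nrow(table)) abort_domain("indicator table is empty")
  method <- match.arg(method)
  qtype <- if (method == "linear") 7 else 1
  inds <- c("nt", "ati", "nddd", "nddd_per_animal_year")

  out <- list()
  keys <- unique(table[c("age_category", "substance_class")])
  cat_rank <- match(keys$age_category, .age_category_table$name)
  cls_rank <- ifelse(keys$substance_class == "TOTAL", "\U0010FFFF",
                     keys$substance_class)
  keys <- keys[order(cat_rank, cls_rank), ]
  for (r in seq_len(nrow(keys))) {
    rows <- table[table$age_category == keys$age_category[r] &
                    table$substance_class == keys$substance_class[r], ]
    for (ind in inds) {
      v <- rows[[ind]]
      q <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = qtype,
                    names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        age_category = keys$age_category[r],
        substance_class = keys$substance_class[r],
        indicator = ind, n_farms = length(v),
        total = sum(v), min = min(v),
        p10 = q[1], p25 = q[2], median = q[3], p75 = q[4], p90 = q[5],
        max = max(v), sd = if (length(v) > 1) sd(v) else 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("amu_summary_table", "data.frame")
  res
}

.log_levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)

.amu_log <- function(level, fmt, ..., log_level = "info") {
  if (.log_levels[[level]] >= .log_levels[[log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline
#'
#' End to end: input (files, in-memory objects, or a fresh simulation),
#' the four inclusion filters (study window, 7-day entry lag, continuous
#' recording, plausibility caps), indicator aggregation, distribution
#' summaries, high-usage benchmarks at the configured fractions under both
#' indicators, and the agreement suite. When `out_dir` is given, all
#' results are written as CSV plus a JSON run manifest recording the seed,
#' configuration and the record counts at every filter stage.
#'
#' @param journal,census,catalog Paths or objects (`amu_journal`,
#'   `amu_census`, `ddd_catalog`). Ignored when `simulate = TRUE`.
#' @param simulate If `TRUE`, generate the inputs with [simulate_amu()].
#' @param sim_cfg Optional [sim_config()] for the simulation (default
#'   `sim_config(seed = seed)`).
#' @param seed Seed for the simulation path; the analysis path itself is
#'   fully deterministic.
#' @param fractions Benchmark fractions (default 0.05, 0.10, 0.25).
#' @param out_dir Optional output directory.
#' @param window_start,window_end Study window.
#' @param max_lag_days Entry-lag cap (default 7).
#' @param rules [plausibility_rules()].
#' @param use_long_acting Enable the long-acting treatment-day multiplier
#'   (default `FALSE`).
#' @param percentile_method Passed to [summarize_indicators()].
#' @param log_level One of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return A list of class `amu_run` with elements `indicators`,
#'   `summary`, `benchmarks` (list of [classify_high_usage()] results),
#'   `agreement` (an `amu_agreement_suite`), `validation` (named list of
#'   per-stage reports), `sim` (the simulation, or `NULL`), `manifest`.
#' @export
run_pipeline <- function(journal = NULL, census = NULL, catalog = NULL,
                         simulate = FALSE, sim_cfg = NULL, seed = 1L,
                         fractions = c(0.05, 0.10, 0.25),
                         out_dir = NULL,
                         window_start = as.Date("2018-10-01"),
                         window_end = as.Date("2019-09-30"),
                         max_lag_days = 7,
                         rules = plausibility_rules(),
                         use_long_acting = FALSE,
                         percentile_method = "linear",
                         log_level = "info") {
  sim <- NULL
  if (simulate) {
    cfg <- sim_cfg %||% sim_config(seed = seed)
    .amu_log("info", "simulating inputs (seed %d)", cfg$seed, log_level = log_level)
    sim <- simulate_amu(cfg)
    j <- sim$journal; cen <- sim$census; catg <- sim$catalog
    window_start <- cfg$window_start; window_end <- cfg$window_end
  } else {
    if (is.null(journal) || is.null(census) || is.null(catalog)) {
      abort_domain("journal, census and catalog are required unless simulate = TRUE")
    }
    j <- if (is.character(journal)) read_journal(journal) else journal
    cen <- if (is.character(census)) read_census(census) else census
    catg <- if (is.character(catalog)) read_ddd_catalog(catalog) else catalog
    stopifnot(inherits(j, "amu_journal"), inherits(cen, "amu_census"),
              inherits(catg, "ddd_catalog"))
  }

  stages <- list()
  step <- function(name, res) {
    .amu_log("info", "filter %-13s in %6d kept %6d rejected %5d", name,
             res$report$n_input, res$report$n_kept, nrow(res$report$rejected),
             log_level = log_level)
    stages[[name]] <<- res$report
    res$journal
  }
  j <- step("window", apply_window_filter(j, window_start, window_end))
  j <- step("entry_lag", apply_entry_lag_filter(j, max_lag_days))
  j <- step("continuity", apply_continuity_filter(j, cen))
  j <- step("plausibility", apply_plausibility_filter(j, rules, catg))

  window_days <- as.numeric(as.Date(window_end) - as.Date(window_start)) + 1
  table <- aggregate_indicators(j, cen, catg,
                                use_long_acting = use_long_acting,
                                window_days = window_days)
  summary <- summarize_indicators(table, method = percentile_method)

  tot <- table[table$substance_class == "TOTAL", ]
  counts <- table(tot$age_category)
  cats <- .age_category_table$name[
    .age_category_table$name %in% names(counts)[counts >= 2]]
  benchmarks <- list()
  for (cat in cats) {
    for (f in sort(fractions)) {
      for (ind in c("ati", "nddd_per_animal_year")) {
        benchmarks[[sprintf("%s_%s_%g", cat, ind, f)]] <-
          classify_high_usage(table, cat, ind, f)
      }
    }
  }
  agreement <- agreement_suite(table, fractions = fractions)

  manifest <- list(
    package = "amubench",
    version = as.character(utils::packageVersion("amubench")),
    seed = if (simulate) (sim_cfg %||% sim_config(seed = seed))$seed else NULL,
    simulated = simulate,
    fractions = sort(fractions),
    window = c(format(as.Date(window_start)), format(as.Date(window_end))),
    filter_stages = lapply(stages, function(s) {
      list(n_input = s$n_input, n_kept = s$n_kept,
           n_rejected = nrow(s$rejected))
    }),
    n_farms = length(unique(cen$farm_id)),
    n_indicator_rows = nrow(table))

  out <- structure(list(indicators = table, summary = summary,
                        benchmarks = benchmarks, agreement = agreement,
                        validation = stages, sim = sim, manifest = manifest),
                   class = "amu_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  invisible(out)
}

#' Write a pipeline result bundle to a directory
#'
#' @param run An `amu_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "amu_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.csv(df, file.path(dir, name),
                                    row.names = FALSE, quote = FALSE)
  write_indicator_table(run$indicators, file.path(dir, "indicators.csv"))
  w(as.data.frame(run$summary), "summary.csv")
  w(do.call(rbind, lapply(run$benchmarks, benchmark_as_df)), "benchmark.csv")
  w(run$agreement$agreement, "agreement.csv")
  w(run$agreement$correlation, "correlation.csv")
  ba_rows <- do.call(rbind, lapply(names(run$agreement$bland_altman), function(cat) {
    d <- run$agreement$bland_altman[[cat]]$data
    cbind(data.frame(age_category = cat, stringsAsFactors = FALSE), d)
  }))
  w(ba_rows, "bland_altman.csv")
  ba_lim <- do.call(rbind, lapply(names(run$agreement$bland_altman), function(cat) {
    b <- run$agreement$bland_altman[[cat]]
    data.frame(age_category = cat, n_farms = b$n, mean_diff = b$mean_diff,
               sd_diff = b$sd_diff, lower = b$lower, upper = b$upper,
               n_outliers = length(b$outliers), stringsAsFactors = FALSE)
  }))
  w(ba_lim, "bland_altman_limits.csv")
  rej <- do.call(rbind, lapply(names(run$validation), function(st) {
    r <- run$validation[[st]]$rejected
    if (!nrow(r)) return(NULL)
    cbind(data.frame(stage = st, stringsAsFactors = FALSE), r)
  }))
  w(rej %||% data.frame(stage = character(0), index = integer(0),
                        event_id = character(0), reason = character(0)),
    "rejections.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(run$sim)) write_simulation(run$sim, file.path(dir, "sim"))
  invisible(dir)
}

# ---- flat key=value config --------------------------------------------

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' coerced to numeric or logical where possible; comma-separated values
#' become vectors.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_amu_config <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_parse(sprintf("config line is not key = value: '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(tolower(parts) %in% c("true", "false"))) tolower(parts) == "true"
      else parts
  }
  out
}

# ---- CLI --------------------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: Rscript -e 'amubench::amu_cli()' <command> [--flag value ...]",
    "",
    "commands:",
    "  simulate   generate synthetic journal/census/catalog/truth CSVs",
    "  validate   run the inclusion filters, write rejection report",
    "  compute    filters + indicator table",
    "  benchmark  high-usage classification from an indicator table",
    "  agree      agreement suite from an indicator table",
    "  summarize  distribution summaries from an indicator table",
    "  run        full pipeline",
    "",
    "flags: --journal --census --catalog --indicators --out-dir --fractions",
    "       --seed --config --log-level --simulate --error-rate --dose-sigma",
    "       --n-farms",
    sep = "\n")
}

.parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) abort_domain(sprintf("unexpected argument: %s", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      out[[key]] <- TRUE            # bare flag
      i <- i + 1
    } else {
      out[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  out
}

.flag_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) return(default)
  as.numeric(strsplit(as.character(opts[[key]]), ",")[[1]])
}

#' Command-line driver
#'
#' Entry point for scripted use, e.g.
#' `Rscript -e 'amubench::amu_cli()' run --simulate --seed 1 --out-dir out`.
#' See `.cli_usage()` output (printed when called without arguments) for
#' the command list. Errors abort with a non-zero exit status under
#' `Rscript`.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return `0L` invisibly on success.
#' @export
amu_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat(.cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[[1]]
  opts <- .parse_flags(args[-1])
  if (!is.null(opts$config)) {
    cfg <- read_amu_config(opts$config)
    for (k in names(cfg)) if (is.null(opts[[k]])) opts[[k]] <- cfg[[k]]
  }
  out_dir <- as.character(opts$out_dir %||% ".")
  log_level <- as.character(opts$log_level %||% "info")
  seed <- as.integer(.flag_num(opts, "seed", 1))
  fractions <- .flag_num(opts, "fractions", c(0.05, 0.10, 0.25))

  sim_cfg_from_opts <- function() {
    base <- sim_config(seed = seed)
    n <- opts$n_farms
    if (!is.null(n)) {
      n <- as.integer(as.numeric(n))
      tot <- 399L + 14L + 190L + 277L
      base <- sim_config(
        n_fattening = max(1L, round(399L * n / tot)),
        n_breeding = max(1L, round(14L * n / tot)),
        n_sow_pool = max(1L, round(190L * n / tot)),
        n_farrow_finish = max(1L, round(277L * n / tot)),
        error_rate = .flag_num(opts, "error_rate", 0),
        dose_sigma = .flag_num(opts, "dose_sigma", 0.3),
        seed = seed)
    } else {
      base <- sim_config(error_rate = .flag_num(opts, "error_rate", 0),
                         dose_sigma = .flag_num(opts, "dose_sigma", 0.3),
                         seed = seed)
    }
    base
  }

  load_inputs <- function() {
    list(j = read_journal(as.character(opts$journal %||%
                                         abort_domain("--journal required"))),
         cen = read_census(as.character(opts$census %||%
                                          abort_domain("--census required"))),
         catg = read_ddd_catalog(as.character(opts$catalog %||%
                                                abort_domain("--catalog required"))))
  }

  switch(cmd,
    simulate = {
      sim <- simulate_amu(sim_cfg_from_opts())
      write_simulation(sim, out_dir)
      .amu_log("info", "wrote simulation to %s", out_dir, log_level = log_level)
    },
    validate = {
      inp <- load_inputs()
      run <- run_pipeline(inp$j, inp$cen, inp$catg, fractions = fractions,
                          out_dir = NULL, log_level = log_level)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      rej <- do.call(rbind, lapply(names(run$validation), function(st) {
        r <- run$validation[[st]]$rejected
        if (!nrow(r)) return(NULL)
        cbind(data.frame(stage = st), r)
      }))
      write.csv(rej %||% data.frame(stage = character(0), index = integer(0),
                                    event_id = character(0),
                                    reason = character(0)),
                file.path(out_dir, "rejections.csv"), row.names = FALSE)
    },
    compute = {
      inp <- load_inputs()
      run <- run_pipeline(inp$j, inp$cen, inp$catg, fractions = fractions,
                          log_level = log_level)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_indicator_table(run$indicators, file.path(out_dir, "indicators.csv"))
    },
    benchmark = {
      tab <- read_indicator_table(as.character(opts$indicators %||%
                                                 abort_domain("--indicators required")))
      tot <- tab[tab$substance_class == "TOTAL", ]
      cats <- unique(tot$age_category)
      res <- list()
      for (cat in cats) for (f in fractions) for (ind in c("ati", "nddd_per_animal_year")) {
        res[[length(res) + 1L]] <-
          benchmark_as_df(classify_high_usage(tab, cat, ind, f))
      }
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(do.call(rbind, res), file.path(out_dir, "benchmark.csv"),
                row.names = FALSE)
    },
    agree = {
      tab <- read_indicator_table(as.character(opts$indicators %||%
                                                 abort_domain("--indicators required")))
      suite <- agreement_suite(tab, fractions = fractions)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(suite$agreement, file.path(out_dir, "agreement.csv"),
                row.names = FALSE)
      write.csv(suite$correlation, file.path(out_dir, "correlation.csv"),
                row.names = FALSE)
    },
    summarize = {
      tab <- read_indicator_table(as.character(opts$indicators %||%
                                                 abort_domain("--indicators required")))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(as.data.frame(summarize_indicators(tab)),
                file.path(out_dir, "summary.csv"), row.names = FALSE)
    },
    run = {
      if (isTRUE(opts$simulate)) {
        run_pipeline(simulate = TRUE, sim_cfg = sim_cfg_from_opts(),
                     seed = seed, fractions = fractions, out_dir = out_dir,
                     log_level = log_level)
      } else {
        inp <- load_inputs()
        run_pipeline(inp$j, inp$cen, inp$catg, fractions = fractions,
                     out_dir = out_dir, log_level = log_level)
      }
    },
    abort_domain(sprintf("unknown command '%s'; run without arguments for usage", cmd))
  )
  invisible(0L)
}
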