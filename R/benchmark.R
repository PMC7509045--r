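# Percentile benchmarking: classify farms as high-usage at a given
# fraction (e.g. the 5, 10 or 25% highest-usage farms of an age category)
# under one indicator.

#' Classify high-usage farms at a percentile fraction
#'
#' Within one age category, farms are ranked descending by the chosen
#' indicator (`TOTAL` rows of the table) and the top
#' `round_half_up(fraction * n)` farms are classified high. Ties straddling
#' the cut are resolved order-free: the whole tie group is included and the
#' classification is flagged (`tie_flag`), so the result never depends on
#' input row order.
#'
#' @param table An `amu_indicator_table` (see [aggregate_indicators()]).
#' @param category One age-category name.
#' @param indicator `"ati"` or `"nddd_per_animal_year"`.
#' @param fraction Benchmark fraction in (0, 1), e.g. 0.05, 0.10, 0.25.
#' @return A list of class `amu_benchmark`: `age_category`, `fraction`,
#'   `indicator`, `farm_id` (all farms), `is_high` (named logical),
#'   `high_farms`, `threshold_value` (indicator value at the cut, `NA` when
#'   the target count is 0), `tie_flag`, `n_farms`.
#' @export
classify_high_usage <- function(table, category,
                                indicator = c("ati", "nddd_per_animal_year"),
                                fraction) {
  stopifnot(inherits(table, "amu_indicator_table"))
  category <- .check_category(category)
  if (!is.character(indicator) ||
      !all(indicator %in% c("ati", "nddd_per_animal_year"))) {
    abort_domain(sprintf("unknown indicator label: %s",
                         paste(setdiff(indicator, c("ati", "nddd_per_animal_year")),
                               collapse = ", ")))
  }
  indicator <- match.arg(indicator)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort_domain("fraction must be a single value in (0, 1)")
  }
  rows <- table[table$age_category == category &
                  table$substance_class == "TOTAL", ]
  n <- nrow(rows)
  if (n < 2) abort_domain(sprintf("fewer than 2 farms in category %s", category))
  if (anyDuplicated(rows$farm_id)) {
    abort_domain("duplicate TOTAL rows per farm in indicator table")
  }
  values <- setNames(rows[[indicator]], rows$farm_id)

  target <- round_half_up(fraction * n)
  if (target == 0) {
    is_high <- setNames(rep(FALSE, n), names(values))
    threshold <- NA_real_
    tie_flag <- FALSE
  } else {
    vsort <- sort(unname(values), decreasing = TRUE)
    threshold <- vsort[target]
    is_high <- values >= threshold
    tie_flag <- sum(is_high) != target
  }
  structure(list(age_category = category, fraction = fraction,
                 indicator = indicator,
                 farm_id = names(values),
                 is_high = is_high,
                 high_farms = sort(names(values)[is_high]),
                 threshold_value = threshold,
                 tie_flag = tie_flag,
                 n_farms = n),
            class = "amu_benchmark")
}

#' @export
print.amu_benchmark <- function(x, ...) {
  cat(sprintf("high-usage classification: %s, %s, fraction %.2f: %d/%d high%s\n",
              x$age_category, x$indicator, x$fraction,
              length(x$high_farms), x$n_farms,
              if (x$tie_flag) " (tie group at cut included)" else ""))
  invisible(x)
}

# flat data frame form used by the CSV interface
benchmark_as_df <- function(x) {
  stopifnot(inherits(x, "amu_benchmark"))
  data.frame(age_category = x$age_category, fraction = x$fraction,
             indicator = x$indicator, farm_id = x$farm_id,
             is_high = unname(x$is_high), tie_flag = x$tie_flag,
             stringsAsFactors = FALSE)
}
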