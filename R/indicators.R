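# The four usage measures per farm x age category x substance class:
# NT (number of treatments), ATI (treatments per animal per year),
# nDDDch (number of defined daily doses), nDDDch/animal/year.

#' Count treatments for one record (NT)
#'
#' One treatment is one application to one animal on one day; for
#' combination products each active agent is evaluated as a treatment.
#' Hence `NT = n_animals * n_days * number of substances`: a group of 20
#' animals treated for 3 days with a single-agent product counts 60
#' treatments.
#'
#' @param rec A [treatment_record()].
#' @param catalog Optional [ddd_catalog()]; only needed when
#'   `use_long_acting = TRUE`.
#' @param use_long_acting If `TRUE`, per-substance treatment days are
#'   scaled by the catalog's long-acting multiplier (adjusting the
#'   treatment duration for depot products). Off by default: the factor
#'   only matters when comparing substances of different pharmaceutical
#'   activity, not when comparing the two indicators.
#' @return Numeric treatment count.
#' @examples
#' r <- treatment_record("F1", "weaned_piglet", c(amoxicillin = 5000), 20, 3)
#' count_treatments(r) # 60
#' @export
count_treatments <- function(rec, catalog = NULL, use_long_acting = FALSE) {
  stopifnot(inherits(rec, "treatment_record"))
  if (!use_long_acting) {
    return(rec$n_animals * rec$n_days * length(rec$substances))
  }
  if (is.null(catalog)) abort_domain("use_long_acting = TRUE needs a catalog")
  laf <- catalog_lookup(catalog, names(rec$substances), "long_acting_factor")
  rec$n_animals * rec$n_days * sum(laf)
}

#' Count defined daily doses for one record (nDDDch)
#'
#' For each active substance, the administered amount in mg is divided by
#' `ddd (mg/kg/day) * SW (kg)`, the defined daily dose at the standard
#' weight of the record's age category.
#'
#' @param rec A [treatment_record()].
#' @param catalog A [ddd_catalog()] covering every substance of the record.
#' @return Named numeric vector of dose counts, one per substance.
#' @examples
#' cat <- ddd_catalog("amoxicillin", 10, "penicillins")
#' r <- treatment_record("F1", "weaned_piglet", c(amoxicillin = 5000), 20, 3)
#' count_nddd(r, cat) # 5000 / (10 * 12) = 41.67
#' @export
count_nddd <- function(rec, catalog) {
  stopifnot(inherits(rec, "treatment_record"))
  ddd <- tryCatch(
    catalog_lookup(catalog, names(rec$substances), "ddd_mg_per_kg"),
    amu_validation_error = function(e) {
      abort_validation(sprintf("record on farm %s (%s): %s",
                               rec$farm_id, rec$age_category, conditionMessage(e)))
    })
  sw <- standard_weight(rec$age_category)
  rec$substances / (ddd * sw)
}

#' Aggregate a journal into an indicator table
#'
#' Sums NT and nDDDch per (farm, age category, substance class) and
#' normalizes both by the census denominator (animals housed for sows,
#' produced for growing categories, per year) to obtain ATI and
#' nDDDch/animal/year. A `TOTAL` class row is emitted for every censused
#' (farm, category) pair, including explicit zero rows for pairs without
#' any treatment, so that zero-usage farms enter the benchmark ranking.
#' Per-class rows are emitted for classes the pair actually used.
#'
#' @param j An `amu_journal` (already filtered; every (farm, category)
#'   appearing in it must have a census entry).
#' @param census An `amu_census`.
#' @param catalog A [ddd_catalog()] covering all substances used.
#' @param use_long_acting Scale treatment days by the catalog's
#'   long-acting multipliers (default `FALSE`; see [count_treatments()]).
#' @param window_days Length of the analysed window in days; denominators
#'   are `animals_per_year * window_days / 365`. The default 365 reproduces
#'   the one-year analysis; sub-year scaling is an extension beyond it.
#' @return A data frame of class `amu_indicator_table` with columns
#'   `farm_id, age_category, substance_class, nt, ati, nddd,
#'   nddd_per_animal_year`, deterministically ordered (farm, category,
#'   class; `TOTAL` last within each group).
#' @export
aggregate_indicators <- function(j, census, catalog,
                                 use_long_acting = FALSE, window_days = 365) {
  stopifnot(inherits(j, "amu_journal"), inherits(census, "amu_census"),
            inherits(catalog, "ddd_catalog"))
  if (!is.numeric(window_days) || window_days <= 0) {
    abort_domain("window_days must be positive")
  }

  key <- function(f, c) paste(f, c, sep = "\r")
  den <- setNames(census$animals_per_year * window_days / 365,
                  key(census$farm_id, census$age_category))

  if (nrow(j)) {
    jk <- key(j$farm_id, j$age_category)
    missing <- unique(jk[!jk %in% names(den)])
    if (length(missing)) {
      abort_validation(sprintf(
        "no census denominator for: %s",
        paste(gsub("\r", "/", missing), collapse = ", ")))
    }
    idx <- match(j$substance, catalog$substance)
    if (anyNA(idx)) {
      abort_validation(sprintf("substance not in catalog: %s",
                               paste(unique(j$substance[is.na(idx)]), collapse = ", ")))
    }
    cls <- catalog$substance_class[idx]
    laf <- if (use_long_acting) catalog$long_acting_factor[idx] else 1
    nt_row <- j$n_animals * j$n_days * laf
    nddd_row <- j$amount_mg /
      (catalog$ddd_mg_per_kg[idx] * standard_weight(j$age_category))
    grp <- interaction(j$farm_id, j$age_category, cls, sep = "\r", drop = TRUE)
    nt_sum <- tapply(nt_row, grp, sum)
    nddd_sum <- tapply(nddd_row, grp, sum)
    parts <- do.call(rbind, strsplit(names(nt_sum), "\r", fixed = TRUE))
    cls_tab <- data.frame(farm_id = parts[, 1], age_category = parts[, 2],
                          substance_class = parts[, 3],
                          nt = as.numeric(nt_sum), nddd = as.numeric(nddd_sum),
                          stringsAsFactors = FALSE)
  } else {
    cls_tab <- data.frame(farm_id = character(0), age_category = character(0),
                          substance_class = character(0),
                          nt = numeric(0), nddd = numeric(0),
                          stringsAsFactors = FALSE)
  }

  # TOTAL rows for every censused pair (zero when no usage)
  if (nrow(cls_tab)) {
    tot_key <- key(cls_tab$farm_id, cls_tab$age_category)
    nt_tot <- tapply(cls_tab$nt, tot_key, sum)
    nddd_tot <- tapply(cls_tab$nddd, tot_key, sum)
  } else {
    nt_tot <- nddd_tot <- setNames(numeric(0), character(0))
  }
  all_keys <- key(census$farm_id, census$age_category)
  tot_tab <- data.frame(farm_id = census$farm_id,
                        age_category = census$age_category,
                        substance_class = "TOTAL",
                        nt = as.numeric(nt_tot[all_keys]),
                        nddd = as.numeric(nddd_tot[all_keys]),
                        stringsAsFactors = FALSE)
  tot_tab$nt[is.na(tot_tab$nt)] <- 0
  tot_tab$nddd[is.na(tot_tab$nddd)] <- 0

  out <- rbind(cls_tab, tot_tab)
  dkey <- key(out$farm_id, out$age_category)
  d <- den[dkey]
  out$ati <- out$nt / d
  out$nddd_per_animal_year <- out$nddd / d
  out <- out[, c("farm_id", "age_category", "substance_class",
                 "nt", "ati", "nddd", "nddd_per_animal_year")]

  cat_rank <- match(out$age_category, .age_category_table$name)
  cls_rank <- ifelse(out$substance_class == "TOTAL", "\U0010FFFF",
                     out$substance_class)
  out <- out[order(out$farm_id, cat_rank, cls_rank), ]
  rownames(out) <- NULL
  class(out) <- c("amu_indicator_table", "data.frame")
  attr(out, "denominators") <- data.frame(
    farm_id = census$farm_id, age_category = census$age_category,
    denominator = unname(den[all_keys]), stringsAsFactors = FALSE)
  out
}

#' Write an indicator table to CSV
#'
#' @param table An `amu_indicator_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  stopifnot(inherits(table, "amu_indicator_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indicator table written by [write_indicator_table()]
#'
#' @param path Path to the CSV.
#' @return An `amu_indicator_table`.
#' @export
read_indicator_table <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm_id", "age_category", "substance_class",
            "nt", "ati", "nddd", "nddd_per_animal_year")
  if (!identical(names(df), need)) {
    abort_schema(sprintf("indicator table header must be exactly: %s",
                         paste(need, collapse = ",")))
  }
  df$farm_id <- as.character(df$farm_id)
  class(df) <- c("amu_indicator_table", "data.frame")
  df
}
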