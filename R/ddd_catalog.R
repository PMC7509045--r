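# Dose-standardization constants: age categories with standard weights,
# the DDD catalog (per-substance defined daily dose + class taxonomy).

.age_category_table <- data.frame(
  name = c("suckling_piglet", "weaned_piglet", "fattening_pig",
           "lactating_sow", "gestating_sow"),
  standard_weight = c(4, 12, 50, 220, 220),
  denominator_kind = c("produced", "produced", "produced", "housed", "housed"),
  stringsAsFactors = FALSE
)

# substance classes of the default taxonomy
.default_classes <- c(
  "polypeptides", "cephalosporins", "penicillins", "fluoroquinolones",
  "aminoglycosides", "macrolides", "tetracyclines", "trimethoprim",
  "sulfonamides", "pleuromutilins"
)

#' Age categories and their standardization constants
#'
#' The five age categories of the monitoring scheme, each with its fixed
#' standard weight at treatment (SW, in kg) and the kind of yearly animal
#' denominator it uses: sows are counted as animals *housed*, the growing
#' categories as animals *produced* per year.
#'
#' @return A data frame with columns `name`, `standard_weight` (kg) and
#'   `denominator_kind` (`"housed"` or `"produced"`).
#' @examples
#' age_categories()
#' @export
age_categories <- function() .age_category_table

#' Substance classes of the default taxonomy
#'
#' @return Character vector of antimicrobial class labels.
#' @export
substance_classes <- function() .default_classes

.check_category <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), .age_category_table$name)
  if (length(bad)) {
    abort_domain(sprintf("unknown age category: %s", paste(bad, collapse = ", ")))
  }
  category
}

#' Standard weight of an age category
#'
#' Fixed assumed body weight at treatment: 4 kg (suckling piglets), 12 kg
#' (weaned piglets), 50 kg (fattening pigs), 220 kg (both sow categories).
#' Used to convert administered active-substance mass into defined daily
#' doses.
#'
#' @param category Character vector of age-category names
#'   (see [age_categories()]).
#' @return Numeric vector of weights in kg.
#' @examples
#' standard_weight("weaned_piglet") # 12
#' @export
standard_weight <- function(category) {
  category <- .check_category(category)
  .age_category_table$standard_weight[match(category, .age_category_table$name)]
}

#' Denominator kind of an age category
#'
#' @inheritParams standard_weight
#' @return `"housed"` (sows) or `"produced"` (growing categories).
#' @export
denominator_kind <- function(category) {
  category <- .check_category(category)
  .age_category_table$denominator_kind[match(category, .age_category_table$name)]
}

#' Construct a DDD catalog
#'
#' A catalog maps each active substance to its defined daily dose
#' (mg per kg body weight per day) and its substance class. An optional
#' long-acting multiplier per substance is carried but ignored unless a
#' computation explicitly opts in (the analysis that motivated this package
#' disregarded long-acting factors; the column is a hook only).
#'
#' Substance identifiers are normalized (trimmed, lower-cased); matching
#' between journal and catalog is exact after normalization.
#'
#' @param substance Character vector of active-substance identifiers.
#' @param ddd_mg_per_kg Numeric, defined daily dose in mg/kg/day; all > 0.
#' @param substance_class Character class label per substance.
#' @param long_acting_factor Numeric multiplier per substance (default 1).
#' @return A data frame of class `ddd_catalog`.
#' @examples
#' ddd_catalog(c("amoxicillin", "doxycycline"), c(20, 10),
#'             c("penicillins", "tetracyclines"))
#' @export
ddd_catalog <- function(substance, ddd_mg_per_kg, substance_class,
                        long_acting_factor = 1) {
  substance <- norm_substance(substance)
  ddd_mg_per_kg <- as.numeric(ddd_mg_per_kg)
  substance_class <- trimws(as.character(substance_class))
  long_acting_factor <- rep_len(as.numeric(long_acting_factor), length(substance))
  long_acting_factor[is.na(long_acting_factor)] <- 1

  if (!length(substance)) abort_validation("catalog has no entries")
  if (anyDuplicated(substance)) {
    dup <- unique(substance[duplicated(substance)])
    abort_validation(sprintf("duplicate substance in catalog: %s",
                             paste(dup, collapse = ", ")))
  }
  bad <- !is.finite(ddd_mg_per_kg) | ddd_mg_per_kg <= 0
  if (any(bad)) {
    abort_validation(sprintf("non-positive ddd for substance: %s",
                             paste(substance[bad], collapse = ", ")))
  }
  if (any(!nzchar(substance_class) | is.na(substance_class))) {
    abort_validation("every substance needs a non-empty substance_class")
  }
  if (any(!is.finite(long_acting_factor) | long_acting_factor <= 0)) {
    abort_validation("long_acting_factor must be positive")
  }
  out <- data.frame(substance = substance,
                    ddd_mg_per_kg = ddd_mg_per_kg,
                    substance_class = substance_class,
                    long_acting_factor = long_acting_factor,
                    stringsAsFactors = FALSE)
  class(out) <- c("ddd_catalog", "data.frame")
  out
}

.catalog_csv_cols <- c("substance", "ddd_mg_per_kg", "substance_class",
                       "long_acting_factor")

#' Read a DDD catalog from CSV
#'
#' Expected header: `substance,ddd_mg_per_kg,substance_class,long_acting_factor`
#' (the last column is optional; blank entries mean 1).
#'
#' @param path Path to the catalog CSV file.
#' @return A [ddd_catalog()].
#' @export
read_ddd_catalog <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("catalog file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- .catalog_csv_cols[1:3]
  if (!identical(names(df)[seq_along(need)], need) ||
      !all(names(df) %in% .catalog_csv_cols)) {
    abort_schema(sprintf(
      "catalog header must be %s (long_acting_factor optional); got: %s",
      paste(.catalog_csv_cols, collapse = ","), paste(names(df), collapse = ",")))
  }
  laf <- if ("long_acting_factor" %in% names(df)) {
    suppressWarnings(as.numeric(ifelse(nzchar(trimws(df$long_acting_factor)),
                                       df$long_acting_factor, NA)))
  } else 1
  ddd <- suppressWarnings(as.numeric(df$ddd_mg_per_kg))
  if (anyNA(ddd)) abort_parse("non-numeric ddd_mg_per_kg in catalog")
  ddd_catalog(df$substance, ddd, df$substance_class, laf)
}

#' Write a DDD catalog to CSV
#'
#' @param catalog A [ddd_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ddd_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ddd_catalog"))
  df <- as.data.frame(catalog)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic example DDD catalog
#'
#' A stand-in catalog shipped with the package for examples, tests and the
#' simulator. The substances and classes follow the default taxonomy, but
#' the mg/kg/day values are *synthetic placeholders of plausible magnitude*,
#' not the national DDD reference values (which are user-supplied input in
#' any real analysis).
#'
#' @return A [ddd_catalog()].
#' @export
amu_example_catalog <- function() {
  path <- system.file("extdata", "ddd_catalog_synthetic.csv",
                      package = "amubench", mustWork = TRUE)
  read_ddd_catalog(path)
}

# internal lookups; error on unknown substances, naming them
catalog_lookup <- function(catalog, substance, what = c("ddd_mg_per_kg",
                           "substance_class", "long_acting_factor")) {
  what <- match.arg(what)
  substance <- norm_substance(substance)
  idx <- match(substance, catalog$substance)
  if (anyNA(idx)) {
    abort_validation(sprintf("substance not in catalog: %s",
                             paste(unique(substance[is.na(idx)]), collapse = ", ")))
  }
  catalog[[what]][idx]
}
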