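# Concordance between the two indicators: percent agreement and Cohen's
# Kappa on high-usage classifications, Spearman's Rho on the continuous
# values, Bland-Altman differences with the +/- 1.96 SD outlier rule.

# accept either an amu_benchmark or a named logical vector of ratings
.as_rating <- function(x) {
  if (inherits(x, "amu_benchmark")) return(x$is_high)
  if (is.logical(x) && !is.null(names(x))) return(x)
  abort_domain("expected an amu_benchmark or a named logical vector")
}

.check_paired_ratings <- function(c1, c2) {
  r1 <- .as_rating(c1); r2 <- .as_rating(c2)
  if (inherits(c1, "amu_benchmark") && inherits(c2, "amu_benchmark")) {
    if (!identical(c1$age_category, c2$age_category) ||
        !identical(c1$fraction, c2$fraction)) {
      abort_domain("classifications differ in age category or fraction")
    }
  }
  if (!setequal(names(r1), names(r2))) {
    abort_domain("classifications cover different farm sets")
  }
  list(r1 = r1[sort(names(r1))], r2 = r2[sort(names(r1))])
}

#' Percent agreement between two high-usage classifications
#'
#' Share of farms given the same high/low label by both classifications,
#' in percent: `100 * (n11 + n00) / n`.
#'
#' @param c1,c2 Two [classify_high_usage()] results (or named logical
#'   vectors) over the same farm set, category and fraction.
#' @return Numeric in \[0, 100\].
#' @export
percent_agreement <- function(c1, c2) {
  r <- .check_paired_ratings(c1, c2)
  100 * mean(r$r1 == r$r2)
}

#' Cohen's Kappa between two high-usage classifications
#'
#' Chance-corrected agreement of the 2x2 high/low table:
#' `k = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the chance agreement from the marginal proportions.
#'
#' When both classifications are constant (both all-high or both all-low)
#' the formula is 0/0; by convention the function then returns 1 for
#' perfect agreement and 0 otherwise, and flags the result with attribute
#' `degenerate = TRUE` so batch runs stay total but auditable.
#'
#' @inheritParams percent_agreement
#' @return Numeric kappa in \[-1, 1\] with logical attribute `degenerate`.
#' @export
cohen_kappa <- function(c1, c2) {
  r <- .check_paired_ratings(c1, c2)
  n <- length(r$r1)
  po <- mean(r$r1 == r$r2)
  p1 <- mean(r$r1); p2 <- mean(r$r2)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (pe >= 1) {
    k <- if (po == 1) 1 else 0
    return(structure(k, degenerate = TRUE))
  }
  structure((po - pe) / (1 - pe), degenerate = FALSE)
}

#' Spearman's rank correlation (mid-rank ties)
#'
#' Pearson correlation of mid-ranks (average ranks for ties) -- the
#' standard tie convention, important here because zero-usage farms create
#' heavy ties at rank bottom.
#'
#' @param x,y Paired numeric vectors of equal length >= 3.
#' @return Numeric rho in \[-1, 1\]. For a constant input vector the
#'   statistic is undefined and `NA` is returned with attribute
#'   `constant_input = TRUE`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_domain("x and y must have equal length")
  if (length(x) < 3) abort_domain("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) abort_domain("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    return(structure(NA_real_, constant_input = TRUE))
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Bland-Altman comparison of the two indicators
#'
#' Per-farm means `(x + y)/2` and differences `x - y` (by convention
#' ATI minus nDDDch/animal/year), sample standard deviation of the
#' differences (n-1 denominator), limits of agreement
#' `mean_diff +/- 1.96 * sd_diff`, and the farms falling outside the
#' limits (the outlier rule). A tiny absolute tolerance proportional to
#' the data scale guards the degenerate all-equal case against
#' floating-point noise.
#'
#' @param x,y Paired numeric vectors (x = ATI, y = nDDDch/animal/year),
#'   length >= 3.
#' @param farm_id Optional identifiers (default `"1"`, `"2"`, ...).
#' @return A list of class `amu_bland_altman`: `data` (data frame
#'   `farm_id, mean, diff, is_outlier`), `mean_diff`, `sd_diff`, `lower`,
#'   `upper`, `outliers` (farm ids), `n`.
#' @export
bland_altman <- function(x, y, farm_id = NULL) {
  if (length(x) != length(y)) abort_domain("x and y must have equal length")
  if (length(x) < 3) abort_domain("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) abort_domain("missing values not allowed")
  farm_id <- as.character(farm_id %||% seq_along(x))
  d <- x - y
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  lower <- mean_diff - 1.96 * sd_diff
  upper <- mean_diff + 1.96 * sd_diff
  eps <- 1e-12 * max(1, abs(x), abs(y))
  is_out <- d < lower - eps | d > upper + eps
  structure(list(data = data.frame(farm_id = farm_id, mean = m, diff = d,
                                   is_outlier = is_out,
                                   stringsAsFactors = FALSE),
                 mean_diff = mean_diff, sd_diff = sd_diff,
                 lower = lower, upper = upper,
                 outliers = farm_id[is_out], n = length(x)),
            class = "amu_bland_altman")
}

#' @export
print.amu_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: n = %d, mean diff = %.4g, sd = %.4g, limits [%.4g, %.4g], %d outlier(s)\n",
    x$n, x$mean_diff, x$sd_diff, x$lower, x$upper, length(x$outliers)))
  invisible(x)
}

#' Full agreement suite over an indicator table
#'
#' For each age category present with at least 2 farms: classifies farms
#' under both indicators at every benchmark fraction and computes percent
#' agreement and Cohen's Kappa; computes Spearman's Rho and the
#' Bland-Altman comparison once per category on the continuous TOTAL
#' values. Output order is deterministic (canonical category order,
#' ascending fractions).
#'
#' @param table An `amu_indicator_table`.
#' @param fractions Benchmark fractions, default `c(0.05, 0.10, 0.25)`.
#' @return A list of class `amu_agreement_suite` with elements
#'   `agreement` (data frame `age_category, fraction, n_farms,
#'   percent_agreement, kappa, degenerate_flag`), `correlation`
#'   (`age_category, n_farms, rho`), and `bland_altman` (named list of
#'   [bland_altman()] results per category).
#' @export
agreement_suite <- function(table, fractions = c(0.05, 0.10, 0.25)) {
  stopifnot(inherits(table, "amu_indicator_table"))
  fractions <- sort(fractions)
  tot <- table[table$substance_class == "TOTAL", ]
  counts <- table(tot$age_category)
  cats <- .age_category_table$name[
    .age_category_table$name %in% names(counts)[counts >= 2]]
  if (!length(cats)) abort_domain("no age category with at least 2 farms")

  agree <- list(); corr <- list(); ba <- list()
  for (cat in cats) {
    rows <- tot[tot$age_category == cat, ]
    rho <- spearman_rho(rows$ati, rows$nddd_per_animal_year)
    corr[[cat]] <- data.frame(age_category = cat, n_farms = nrow(rows),
                              rho = as.numeric(rho), stringsAsFactors = FALSE)
    ba[[cat]] <- bland_altman(rows$ati, rows$nddd_per_animal_year,
                              rows$farm_id)
    for (f in fractions) {
      c1 <- classify_high_usage(table, cat, "ati", f)
      c2 <- classify_high_usage(table, cat, "nddd_per_animal_year", f)
      k <- cohen_kappa(c1, c2)
      agree[[paste(cat, f)]] <- data.frame(
        age_category = cat, fraction = f, n_farms = nrow(rows),
        percent_agreement = percent_agreement(c1, c2),
        kappa = as.numeric(k),
        degenerate_flag = isTRUE(attr(k, "degenerate")),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(agreement = do.call(rbind, unname(agree)),
                 correlation = do.call(rbind, unname(corr)),
                 bland_altman = ba),
            class = "amu_agreement_suite")
}
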