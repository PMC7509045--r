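mk_ratings <- function(high1, high2, n) {
  farms <- sprintf("F%03d", seq_len(n))
  list(r1 = setNames(seq_len(n) %in% high1, farms),
       r2 = setNames(seq_len(n) %in% high2, farms))
}

test_that("percent agreement counts matching classifications", {
  r <- mk_ratings(1:5, 1:5, 50)
  expect_equal(percent_agreement(r$r1, r$r2), 100)

  r <- mk_ratings(1:10, 11:20, 20)        # complementary
  expect_equal(percent_agreement(r$r1, r$r2), 0)

  r <- mk_ratings(1:10, 1:7, 100)         # exactly 3 farms rated differently
  expect_equal(percent_agreement(r$r1, r$r2), 97)

  # mismatched farm sets -> domain error
  a <- setNames(c(TRUE, FALSE), c("A", "B"))
  b <- setNames(c(TRUE, FALSE), c("A", "C"))
  expect_error(percent_agreement(a, b), class = "amu_domain_error")
})

test_that("Cohen's kappa evaluates the 2x2 formula", {
  # identical, both classes present -> 1
  r <- mk_ratings(1:5, 1:5, 50)
  expect_equal(as.numeric(cohen_kappa(r$r1, r$r2)), 1)
  expect_false(attr(cohen_kappa(r$r1, r$r2), "degenerate"))

  # n11=8, n10=2, n01=2, n00=88: p_o = 0.96,
  # p_e = 0.1*0.1 + 0.9*0.9 = 0.82, k = 0.14/0.18 (verified by hand)
  r <- mk_ratings(1:10, c(1:8, 11:12), 100)
  expect_equal(as.numeric(cohen_kappa(r$r1, r$r2)), 0.14 / 0.18,
               tolerance = 1e-12)

  # constant raters: perfect agreement -> 1 with degeneracy flag
  r <- mk_ratings(integer(0), integer(0), 30)
  k <- cohen_kappa(r$r1, r$r2)
  expect_equal(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
  r <- mk_ratings(1:30, 1:30, 30)
  expect_true(attr(cohen_kappa(r$r1, r$r2), "degenerate"))
})

test_that("kappa matches direct formula evaluation on random 2x2 tables", {
  set.seed(2024)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, size = sample(10:400, 1),
                                        prob = runif(4, 0.05, 1)))
    n11 <- cells[1]; n10 <- cells[2]; n01 <- cells[3]; n00 <- cells[4]
    n <- sum(cells)
    r1 <- setNames(rep(c(TRUE, TRUE, FALSE, FALSE), cells), sprintf("F%d", 1:n))
    r2 <- setNames(rep(c(TRUE, FALSE, TRUE, FALSE), cells), sprintf("F%d", 1:n))
    po <- (n11 + n00) / n
    pe <- ((n11 + n10) / n) * ((n11 + n01) / n) +
      ((n01 + n00) / n) * ((n10 + n00) / n)
    k <- cohen_kappa(r1, r2)
    if (pe < 1) {
      expect_equal(as.numeric(k), (po - pe) / (1 - pe), tolerance = 1e-12)
      expect_lte(as.numeric(k), 1)
    } else {
      expect_true(attr(k, "degenerate"))
    }
    # rater symmetry
    expect_equal(as.numeric(cohen_kappa(r2, r1)), as.numeric(k))
  }
})

test_that("spearman_rho: rank invariance, reversal, hand-derived value", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, exp(x / 10)), 1)   # increasing transform
  expect_equal(spearman_rho(x, -x), -1)
  # d^2 sum = 4 -> 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4)), 0.8)

  const <- spearman_rho(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(const))
  expect_true(attr(const, "constant_input"))
  expect_error(spearman_rho(1:2, 1:2), class = "amu_domain_error")
})

test_that("spearman_rho equals the independent rank oracle with ties", {
  set.seed(77)
  # exhaustive on short tied vectors, random beyond
  grid3 <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  for (i in seq_len(nrow(grid3))) {
    for (j in seq_len(nrow(grid3))) {
      x <- grid3[i, ]; y <- grid3[j, ]
      mine <- spearman_rho(x, y)
      ref <- suppressWarnings(stats::cor(x, y, method = "spearman"))
      if (is.na(ref)) expect_true(is.na(mine))
      else expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
    }
  }
  for (rep in 1:300) {
    n <- sample(4:12, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    if (is.na(ref)) expect_true(is.na(mine))
    else expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
  }
})

test_that("bland_altman computes limits and outliers as stated", {
  # identity
  ba <- bland_altman(1:5, 1:5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(length(ba$outliers), 0)

  # hand computation: diffs (0,0,0,0,10): mean 2, sd sqrt(20),
  # limits 2 +/- 1.96*sqrt(20) = [-6.7654, 10.7654] -> 10 is inside
  ba <- bland_altman(c(1, 2, 3, 4, 15), c(1, 2, 3, 4, 5))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, sqrt(20))
  expect_equal(ba$lower, 2 - 1.96 * sqrt(20))
  expect_equal(ba$upper, 2 + 1.96 * sqrt(20))
  expect_length(ba$outliers, 0)

  # a genuinely extreme farm is flagged
  ba <- bland_altman(c(rep(0, 19), 10), rep(0, 20), sprintf("F%d", 1:20))
  expect_equal(ba$outliers, "F20")

  expect_error(bland_altman(1:2, 1:2), class = "amu_domain_error")
})

test_that("bland_altman limits contain about 95% of normal differences", {
  set.seed(31415)
  n <- 10000
  d <- rnorm(n)
  ba <- bland_altman(d, rep(0, n))
  frac_out <- length(ba$outliers) / n
  expect_gte(frac_out, 0.04)
  expect_lte(frac_out, 0.06)
})

test_that("agreement_suite: identity limit and output cardinality", {
  set.seed(99)
  tabs <- lapply(age_categories()$name, function(cat) {
    fix_table(ati = runif(30), category = cat)
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("amu_indicator_table", "data.frame")
  suite <- agreement_suite(tab, fractions = c(0.05, 0.10, 0.25))
  expect_equal(nrow(suite$agreement), 15)    # 5 categories x 3 fractions
  expect_length(suite$bland_altman, 5)
  expect_equal(nrow(suite$correlation), 5)
  expect_true(all(suite$agreement$percent_agreement == 100))
  expect_true(all(suite$agreement$kappa == 1))
  expect_true(all(suite$correlation$rho == 1))
  expect_true(all(vapply(suite$bland_altman,
                         function(b) length(b$outliers) == 0, logical(1))))
  # every farm in n_farms appears exactly once in the per-farm output
  for (cat in names(suite$bland_altman)) {
    b <- suite$bland_altman[[cat]]
    expect_equal(nrow(b$data), suite$correlation$n_farms[
      suite$correlation$age_category == cat])
    expect_false(anyDuplicated(b$data$farm_id) > 0)
  }
})
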