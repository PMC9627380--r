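test_that("the normality gate admits normal samples and rejects heavy tails", {
  withr::local_seed(101)
  x <- rnorm(100); y <- rnorm(100, 1)
  expect_true(normality_gate(x, y))
  expect_false(normality_gate(rcauchy(200), rnorm(200)))
  expect_false(normality_gate(rep(3, 10), rnorm(10)))  # zero variance
  expect_error(normality_gate(c(1, 2), rnorm(10)), "insufficient")
})

test_that("compare_continuous picks the branch the gate dictates", {
  withr::local_seed(102)
  x <- rnorm(60, 10, 2); y <- rnorm(60, 10, 2)
  res <- compare_continuous(x, x, predictor = "self")
  expect_identical(res$test_used, "t_test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$selected)

  skewed <- compare_continuous(rexp(200), rexp(200))
  expect_identical(skewed$test_used, "mann_whitney")

  expect_error(compare_continuous(c(1, 2), y), "insufficient")

  # group summaries are plain mean +/- SD
  r2 <- compare_continuous(x, y)
  expect_equal(r2$mean_poor, mean(x))
  expect_equal(r2$sd_good, sd(y))
})

test_that("normal but heteroscedastic groups stay on the t branch (Welch)", {
  withr::local_seed(103)
  x <- rnorm(150, 0, 1); y <- rnorm(150, 0, 4)
  res <- compare_continuous(x, y)
  expect_identical(res$test_used, "t_test")
})

test_that("chi-square matches a from-scratch Pearson oracle on random tables", {
  withr::local_seed(104)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 40) + 5, 2, 2)
    res <- compare_categorical(tab)
    oracle <- pearson_chisq(tab)
    if (res$test_used == "chi_square") {
      expect_equal(res$statistic, oracle$statistic, tolerance = 1e-10)
      expect_equal(res$p_value, oracle$p_value, tolerance = 1e-10)
    }
  }
})

test_that("the published age contingency is decisively significant", {
  tab <- rbind(poor = c(34, 20, 24), good = c(15, 31, 44))
  res <- compare_categorical(tab, predictor = "age")
  expect_identical(res$test_used, "chi_square")
  expect_lt(res$p_value, 0.001)
  expect_true(res$selected)
  expect_equal(res$p_value, pearson_chisq(tab)$p_value, tolerance = 1e-10)
})

test_that("degenerate and sparse tables are handled explicitly", {
  even <- rbind(c(30, 30), c(10, 10))
  res <- compare_categorical(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  sparse <- rbind(c(2, 30), c(3, 25))
  expect_identical(compare_categorical(sparse)$test_used, "fisher_exact")

  big_sparse <- rbind(c(2, 30, 40), c(3, 25, 35))
  expect_warning(res3 <- compare_categorical(big_sparse), "expected count")
  expect_identical(res3$test_used, "chi_square")

  expect_error(compare_categorical(rbind(c(0, 0), c(5, 5))), "degenerate")
  expect_error(compare_categorical(matrix(5, 1, 2)), "2x2")
  expect_error(compare_categorical(rbind(c(-1, 5), c(5, 5))), "non-negative")
})

test_that("ordinal coding follows the severity order of the grading bins", {
  d <- tibble::tibble(
    age = c(30, 46, 59, 60),
    gcs = c(15, 12, 8, 3),
    damaged_area = c("parietal", "occipital", "temporal", "frontal"),
    marshall = c("I", "III", "V", "VI"),
    crp = c(5, 10, 15, 20),
    il8 = c(5, 10, 20, 30),
    apoe_e4_carrier = c(FALSE, TRUE, TRUE, FALSE)
  )
  enc <- encode_ordinal(d, names(d))
  expect_identical(enc$age, c(1L, 2L, 2L, 3L))
  expect_identical(enc$gcs, c(1L, 2L, 3L, 3L))
  expect_identical(enc$damaged_area, c(1L, 2L, 3L, 4L))
  expect_identical(enc$marshall, c(1L, 3L, 5L, 6L))
  expect_identical(enc$crp, c(1L, 2L, 3L, 3L))
  expect_identical(enc$il8, c(1L, 2L, 3L, 3L))
  expect_identical(enc$apoe_e4_carrier, c(0L, 1L, 1L, 0L))
  expect_error(encode_ordinal(d, "bmi"), "not present")
})

test_that("a single binary predictor recovers the cross-product odds ratio", {
  # closed form: univariate binary logistic OR = ad/bc of the 2x2 table
  counts <- c(a = 30, b = 18, c = 12, d = 40)  # poor/carrier layout
  d <- tibble::tibble(
    apoe_e4_carrier = rep(c(TRUE, TRUE, FALSE, FALSE),
                          times = counts),
    outcome = rep(c("poor", "good", "poor", "good"), times = counts)
  )
  fit <- fit_risk_model(d, "apoe_e4_carrier")
  td <- tidy(fit)
  expect_equal(td$odds_ratio,
               (counts["a"] * counts["d"]) / (counts["b"] * counts["c"]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(td$ci_lower <= td$odds_ratio && td$odds_ratio <= td$ci_upper)
  expect_equal(td$odds_ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_identical(gl$n, nrow(d))
  expect_true(gl$converged)
})

test_that("perfect separation raises an explicit error", {
  d <- tibble::tibble(
    crp = c(rep(30, 20), rep(1, 20)),
    outcome = rep(c("poor", "good"), each = 20)
  )
  expect_error(fit_risk_model(d, "crp"), "separation")
})

test_that("select_predictors keeps multivariate-significant candidates in order", {
  uni <- tibble::tibble(predictor = c("a", "b", "c", "d"),
                        selected = c(TRUE, TRUE, TRUE, FALSE))
  multi <- tibble::tibble(predictor = c("a", "b", "c"),
                          p_value = c(0.01, 0.20, 0.002))
  expect_identical(select_predictors(uni, multi), c("a", "c"))
  expect_identical(
    select_predictors(uni[0, ], multi[0, ]),
    character()
  )
})

test_that("screening a default synthetic cohort keeps the strongest predictors", {
  # property: {gcs, marshall} are jointly retained in >= 90% of seeds;
  # with 30 seeds we allow two binomial SDs (sqrt(.9*.1/30) ~ 0.055)
  # below that rate so the check fails for real power loss, not MC noise
  hits <- vapply(1:30, function(s) {
    co <- generate_cohort(168, seed = 500 + s)
    sel <- suppressWarnings(screen_predictors(co)$selected)
    all(c("gcs", "marshall") %in% sel)
  }, logical(1))
  expect_gte(mean(hits), 0.9 - 2 * sqrt(0.9 * 0.1 / 30))
})

test_that("screening requires complete outcome labels", {
  co <- generate_cohort(50, seed = 1)
  co$outcome[3] <- NA
  expect_error(screen_predictors(co), "outcome")
  expect_error(fit_risk_model(co, "crp"), "outcome")
})
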