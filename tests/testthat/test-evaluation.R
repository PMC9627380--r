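test_that("trapezoidal AUC equals tie-adjusted pair counting", {
  withr::local_seed(201)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c("poor", "good", sample(c("poor", "good"), n - 2, TRUE))
    scores <- sample(10:33, n, replace = TRUE)  # integer scores force ties
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, pair_counting_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(202)
  for (i in 1:10) {
    labels <- sample(c("poor", "good"), 80, TRUE)
    scores <- rnorm(80) + (labels == "poor")
    ours <- roc_curve(scores, labels)$auc
    ref <- as.numeric(pROC::auc(
      pROC::roc(response = labels, predictor = scores,
                levels = c("good", "poor"), direction = "<", quiet = TRUE)
    ))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("ROC endpoints and monotonicity hold on random instances", {
  withr::local_seed(203)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    labels <- c("poor", "good", sample(c("poor", "good"), n - 2, TRUE))
    scores <- round(rnorm(n, 20, 5))
    pts <- roc_curve(scores, labels)$points
    expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
    expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
    # thresholds ascend; sensitivity falls, specificity rises
    expect_true(all(diff(pts$threshold) > 0))
    expect_true(all(diff(pts$sensitivity) <= 0))
    expect_true(all(diff(pts$specificity) >= 0))
  }
})

test_that("degenerate score patterns give the textbook AUCs", {
  perfect <- roc_curve(c(30, 31, 12, 13),
                       c("poor", "poor", "good", "good"))
  expect_equal(perfect$auc, 1)
  ties <- roc_curve(rep(20, 10), rep(c("poor", "good"), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_curve(1:5, rep("poor", 5)), "both outcome classes")
  expect_error(roc_curve(1:3, c("poor", "good", "bad")), "labels")
})

test_that("the AUC confidence interval matches the Hanley-McNeil closed form", {
  withr::local_seed(204)
  labels <- sample(c("poor", "good"), 100, TRUE)
  scores <- rnorm(100) + 1.2 * (labels == "poor")
  roc <- roc_curve(scores, labels)
  a <- roc$auc
  n1 <- roc$n_poor; n2 <- roc$n_good
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
               (n1 * n2))
  expect_equal(unname(roc$auc_ci),
               c(max(0, a - qnorm(0.975) * se), min(1, a + qnorm(0.975) * se)),
               tolerance = 1e-12)
  expect_true(roc$auc_ci[1] <= a && a <= roc$auc_ci[2])
})

test_that("the Youden threshold maximises J with the documented tie-breaks", {
  # brute-force oracle over every swept threshold
  withr::local_seed(205)
  co <- score_cohort(generate_cohort(50, seed = 205))
  roc <- roc_curve(co$total, co$outcome)
  pts <- roc$points
  j <- pts$sensitivity + pts$specificity - 1
  best_j <- max(j)
  chosen <- youden_threshold(roc)
  expect_equal(j[pts$threshold == chosen], best_j)
  cands <- pts[j == best_j, ]
  cands <- cands[cands$specificity == max(cands$specificity), ]
  expect_equal(chosen, max(cands$threshold))

  # perfect separation: the single J = 1 midpoint
  perfect <- roc_curve(c(30, 31, 12, 13), c("poor", "poor", "good", "good"))
  expect_equal(youden_threshold(perfect), 21.5)

  # all ties: J = 0 everywhere, tie-break lands on the above-max sentinel
  ties <- roc_curve(rep(20, 10), rep(c("poor", "good"), 5))
  expect_equal(youden_threshold(ties), 20.5)
})

test_that("confusion metrics match a brute-force recount", {
  simple <- confusion_metrics(c(19, 24), c("good", "poor"), 23.5)
  expect_equal(simple$accuracy, 1)
  expect_equal(simple$sensitivity, 1)
  expect_equal(simple$specificity, 1)
  flipped <- confusion_metrics(c(19, 24), c("poor", "good"), 23.5)
  expect_equal(flipped$accuracy, 0)

  co <- score_cohort(generate_cohort(500, seed = 206))
  m <- confusion_metrics(co$total, co$outcome, 23.5)
  pred <- ifelse(co$total > 23.5, "poor", "good")
  expect_identical(m$tp, sum(pred == "poor" & co$outcome == "poor"))
  expect_identical(m$fp, sum(pred == "poor" & co$outcome == "good"))
  expect_identical(m$tn, sum(pred == "good" & co$outcome == "good"))
  expect_identical(m$fn, sum(pred == "good" & co$outcome == "poor"))
  expect_equal(m$accuracy, mean(pred == co$outcome))
  expect_equal(m$tp + m$fp + m$tn + m$fn, 500L, ignore_attr = TRUE)

  # invariance to patient order
  perm <- sample(500)
  m2 <- confusion_metrics(co$total[perm], co$outcome[perm], 23.5)
  expect_equal(m, m2)
  expect_error(confusion_metrics(numeric(), character(), 23.5), "empty")
})

test_that("evaluate_model freezes the threshold chosen on training data", {
  sets <- split_cohort(generate_cohort(500, seed = 207), c(200, 150, 100, 50),
                       seed = 207)
  ev <- evaluate_model(sets$part2, sets$validation, sets$testing,
                       threshold = NULL)
  scored_train <- score_cohort(sets$part2)
  expect_equal(ev$threshold,
               youden_threshold(roc_curve(scored_train$total,
                                          scored_train$outcome)))
  # validation metrics are computed at the frozen threshold, not their own
  scored_val <- score_cohort(sets$validation)
  expect_equal(
    ev$sets$validation$metrics,
    confusion_metrics(scored_val$total, scored_val$outcome, ev$threshold)
  )
  df <- tidy(ev)
  expect_identical(df$set, c("training", "validation", "testing"))
  expect_true(all(df$auc > 0.6))
})

test_that("evaluating the training set as validation duplicates its metrics", {
  co <- generate_cohort(200, seed = 208)
  ev <- evaluate_model(co, co, threshold = 23.5)
  df <- tidy(ev)
  expect_equal(df[1, -1], df[2, -1], ignore_attr = TRUE)
})

test_that("label permutation destroys the signal", {
  co <- score_cohort(generate_cohort(400, seed = 209))
  perm <- withr::with_seed(209, sample(nrow(co)))
  roc <- roc_curve(co$total, co$outcome[perm])
  # null sampling error for the concordance statistic
  se <- sqrt((roc$n_poor + roc$n_good + 1) / (12 * roc$n_poor * roc$n_good))
  expect_lt(abs(roc$auc - 0.5), 3 * se)
})

test_that("evaluation plots build without error", {
  co <- score_cohort(generate_cohort(120, seed = 210))
  roc <- roc_curve(co$total, co$outcome)
  expect_s3_class(ggplot2::autoplot(roc), "ggplot")
  ev <- evaluate_model(co, threshold = 23.5)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_s3_class(plot_score_distribution(co), "ggplot")
})
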