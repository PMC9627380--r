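#' ROC curve of a prognostic score
#'
#' Sweeps decision thresholds at the midpoints between consecutive
#' distinct scores, plus sentinel thresholds half a point below the
#' minimum and above the maximum so the (1, 0) and (0, 1) endpoints always
#' exist. A patient is predicted poor iff score > threshold ("positive" =
#' poor prognosis). AUC is the trapezoidal area, which for this
#' construction equals the tie-adjusted concordance probability (ties
#' count one half); its 95% CI uses the Hanley-McNeil standard error with
#' a normal approximation, clipped to \[0, 1\].
#'
#' @param scores Numeric score per patient (higher = more severe).
#' @param labels Outcome per patient, `"poor"`/`"good"` (factor or
#'   character); both classes must be present.
#' @return An object of class `eppm_roc`: `points` tibble (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_ci` (length-2), `n_poor`,
#'   `n_good`. Use [tidy()] for the points and [glance()] for the AUC row.
#' @examples
#' cohort <- score_cohort(generate_cohort(100, seed = 3))
#' roc <- roc_curve(cohort$total, cohort$outcome)
#' glance(roc)
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  ok <- labels %in% c("poor", "good")
  if (!all(ok)) stop("labels must be 'poor' or 'good'", call. = FALSE)
  poor <- labels == "poor"
  n_poor <- sum(poor)
  n_good <- sum(!poor)
  if (n_poor == 0 || n_good == 0) {
    stop("ROC undefined: both outcome classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 0.5,
                  if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
                  s[length(s)] + 0.5)
  sens <- vapply(thresholds, function(t) sum(scores > t & poor) / n_poor,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores <= t & !poor) / n_good,
                 numeric(1))
  points <- tibble::tibble(
    threshold = thresholds, sensitivity = sens, specificity = spec
  )
  # trapezoid over the ROC polyline ordered by increasing FPR
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(
    list(
      points = points,
      auc = auc,
      auc_ci = hanley_mcneil_ci(auc, n_poor, n_good),
      n_poor = n_poor,
      n_good = n_good
    ),
    class = "eppm_roc"
  )
}

# Hanley-McNeil closed-form SE of a trapezoidal AUC
hanley_mcneil_ci <- function(auc, n_poor, n_good, level = 0.95) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_poor - 1) * (q1 - auc^2) +
                (n_good - 1) * (q2 - auc^2)) / (n_poor * n_good))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' @export
print.eppm_roc <- function(x, ...) {
  ci <- x$auc_ci
  cat(sprintf("<eppm_roc> AUC %.3f (95%% CI %.3f-%.3f), %d poor / %d good\n",
              x$auc, ci[1], ci[2], x$n_poor, x$n_good))
  invisible(x)
}

#' @rdname roc_curve
#' @param x An `eppm_roc`.
#' @param ... Unused.
#' @export
tidy.eppm_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @export
glance.eppm_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_lower = x$auc_ci[["lower"]],
    auc_upper = x$auc_ci[["upper"]], n_poor = x$n_poor, n_good = x$n_good
  )
}

#' Youden-optimal decision threshold from a ROC curve
#'
#' Returns the threshold maximising the Youden index
#' J = sensitivity + specificity - 1; ties are broken toward higher
#' specificity, then toward the higher threshold.
#'
#' @param roc An `eppm_roc` from [roc_curve()].
#' @return The optimal threshold (numeric scalar).
#' @export
youden_threshold <- function(roc) {
  pts <- roc$points
  j <- pts$sensitivity + pts$specificity - 1
  best <- pts[order(-j, -pts$specificity, -pts$threshold), ]
  best$threshold[1]
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Classifies each patient poor iff score > threshold and tabulates the
#' result against the true labels ("positive" = poor prognosis).
#'
#' @param scores Numeric scores.
#' @param labels `"poor"`/`"good"` per patient.
#' @param threshold Decision threshold (the published model uses 23.5).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 23.5) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  pred_poor <- scores > threshold
  is_poor <- labels == "poor"
  tp <- sum(pred_poor & is_poor)
  fp <- sum(pred_poor & !is_poor)
  tn <- sum(!pred_poor & !is_poor)
  fn <- sum(!pred_poor & is_poor)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

#' Evaluate the EPPM on training, validation and testing cohorts
#'
#' Scores every cohort with the grading rules (all seven predictors),
#' then reports per-set ROC, AUC with its 95% CI, and confusion metrics
#' at a single fixed threshold. The threshold is chosen on the training
#' set only (Youden-optimal if not supplied) and then frozen, so
#' validation and testing metrics never depend on re-optimising against
#' their own labels.
#'
#' @param train,validation,testing Labelled cohorts (data frames); the
#'   latter two optional.
#' @param rules Grading rules.
#' @param threshold Fixed decision threshold; `NULL` selects the
#'   Youden-optimal threshold on `train`.
#' @return An object of class `eppm_evaluation`: the frozen `threshold`
#'   and a per-set list of `roc` and `metrics`. [tidy()] returns one row
#'   per set.
#' @examples
#' sets <- split_cohort(generate_cohort(250, seed = 2), c(100, 100, 50, 0))
#' ev <- evaluate_model(sets$part2, sets$validation, threshold = 23.5)
#' tidy(ev)
#' @export
evaluate_model <- function(train, validation = NULL, testing = NULL,
                           rules = default_rules(), threshold = 23.5) {
  sets <- list(training = train, validation = validation, testing = testing)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  scored <- purrr::map(sets, function(d) {
    if (!"outcome" %in% names(d) || anyNA(d$outcome)) {
      stop("evaluate_model() needs outcome labels on every record",
           call. = FALSE)
    }
    score_cohort(d, rules)
  })
  train_roc <- roc_curve(scored$training$total, scored$training$outcome)
  if (is.null(threshold)) threshold <- youden_threshold(train_roc)
  results <- purrr::map(scored, function(d) {
    list(
      roc = roc_curve(d$total, d$outcome),
      metrics = confusion_metrics(d$total, d$outcome, threshold)
    )
  })
  structure(
    list(threshold = threshold, sets = results),
    class = "eppm_evaluation"
  )
}

#' @rdname evaluate_model
#' @param x An `eppm_evaluation`.
#' @param ... Unused.
#' @export
tidy.eppm_evaluation <- function(x, ...) {
  purrr::imap_dfr(x$sets, function(res, nm) {
    dplyr::bind_cols(
      tibble::tibble(set = nm, threshold = x$threshold),
      glance(res$roc),
      res$metrics
    )
  })
}

#' @export
print.eppm_evaluation <- function(x, ...) {
  cat("<eppm_evaluation> threshold =", x$threshold, "\n")
  df <- tidy(x)
  print(dplyr::select(df, "set", "auc", "auc_lower", "auc_upper",
                      "accuracy", "sensitivity", "specificity"))
  invisible(x)
}
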