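#' Normality gate for choosing parametric vs rank-based comparison
#'
#' Applies the Shapiro-Wilk test to each outcome group; the parametric
#' branch (Student's t) is allowed only when both groups are compatible
#' with normality (p >= `alpha_norm` in both). A zero-variance group is
#' degenerate and fails the gate by convention.
#'
#' @param x,y Numeric values for the two outcome groups (>= 3 each).
#' @param alpha_norm Significance level for the Shapiro-Wilk test.
#' @return `TRUE` if both groups pass, else `FALSE`.
#' @export
normality_gate <- function(x, y, alpha_norm = 0.05) {
  for (v in list(x, y)) {
    if (length(v) < 3) {
      stop("insufficient data: normality gate needs >= 3 values per group",
           call. = FALSE)
    }
  }
  passes <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    # shapiro.test is defined for 3 <= n <= 5000; subsample above that
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    stats::shapiro.test(v)$p.value >= alpha_norm
  }
  passes(x) && passes(y)
}

# Brown-Forsythe variance-homogeneity check (Levene with median centring)
levene_p <- function(x, y) {
  d <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (stats::sd(d) == 0) return(1)
  stats::oneway.test(d ~ g, var.equal = TRUE)$p.value
}

#' Compare a continuous predictor between outcome groups
#'
#' Normality-gated two-sided comparison: Student's t-test when both groups
#' pass the Shapiro-Wilk gate (pooled variance if a Brown-Forsythe check
#' accepts homogeneity, Welch otherwise), Mann-Whitney rank test when the
#' gate fails. Group summaries are reported as mean +/- SD.
#'
#' @param x,y Numeric values for the poor and good outcome groups.
#' @param alpha Significance level for selection.
#' @param alpha_norm Level for the normality gate.
#' @param predictor Optional predictor name carried into the result.
#' @return One-row tibble: `predictor`, `test_used` (`t_test` or
#'   `mann_whitney`), `statistic`, `p_value`, `mean_poor`, `sd_poor`,
#'   `mean_good`, `sd_good`, `selected` (`p_value < alpha`).
#' @export
compare_continuous <- function(x, y, alpha = 0.05, alpha_norm = 0.05,
                               predictor = NA_character_) {
  if (length(x) < 3 || length(y) < 3) {
    stop("insufficient data: need >= 3 values per group", call. = FALSE)
  }
  normal <- normality_gate(x, y, alpha_norm)
  if (normal) {
    var_equal <- levene_p(x, y) >= alpha
    ht <- stats::t.test(x, y, var.equal = var_equal)
    test_used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test_used <- "mann_whitney"
  }
  p <- unname(ht$p.value)
  tibble::tibble(
    predictor = predictor,
    test_used = test_used,
    statistic = unname(ht$statistic),
    p_value = p,
    mean_poor = mean(x), sd_poor = stats::sd(x),
    mean_good = mean(y), sd_good = stats::sd(y),
    selected = p < alpha
  )
}

#' Compare a categorical predictor between outcome groups
#'
#' Pearson chi-square without continuity correction on the outcome x
#' category contingency table; when any expected count is below 5 the test
#' falls back to Fisher's exact test for 2x2 tables, or keeps the
#' chi-square with a warning for larger tables.
#'
#' @param tab Contingency matrix, rows = outcome (poor, good), columns =
#'   predictor categories; at least 2x2.
#' @param alpha Significance level for selection.
#' @param predictor Optional predictor name carried into the result.
#' @return One-row tibble: `predictor`, `test_used` (`chi_square` or
#'   `fisher_exact`), `statistic` (`NA` for Fisher), `p_value`, `counts`
#'   (list-column holding the table), `selected`.
#' @export
compare_categorical <- function(tab, alpha = 0.05, predictor = NA_character_) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least a 2x2 contingency table", call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) && all(dim(tab) == 2)) {
    ht <- stats::fisher.test(tab)
    test_used <- "fisher_exact"
    statistic <- NA_real_
  } else {
    if (any(expected < 5)) {
      warning("expected count < 5 in a table larger than 2x2; ",
              "chi-square approximation may be poor", call. = FALSE)
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    test_used <- "chi_square"
    statistic <- unname(ht$statistic)
  }
  p <- unname(ht$p.value)
  tibble::tibble(
    predictor = predictor,
    test_used = test_used,
    statistic = statistic,
    p_value = p,
    counts = list(tab),
    selected = p < alpha
  )
}

# severity-ordered integer coding used by the multivariate model: one
# coefficient per predictor, interpreted per one-level increase
ordinal_codings <- function() {
  list(
    age = function(x) findInterval(x, c(46, 60)) + 1L,     # <=45,46-59,>=60
    gcs = function(x) 3L - findInterval(x, c(9, 13)),      # 13-15,9-12,<=8
    damaged_area = function(x) {
      match(x, c("parietal", "occipital", "temporal", "frontal"))
    },
    apoe_e4_carrier = function(x) as.integer(x),
    crp = function(x) findInterval(x, c(10, 15)) + 1L,     # <10,10-15,>=15
    il8 = function(x) findInterval(x, c(10, 20)) + 1L,     # <10,10-20,>=20
    marshall = function(x) match(x, c("I", "II", "III", "IV", "V", "VI")),
    sex = function(x) as.integer(x == "male"),
    smoking = function(x) as.integer(x),
    alcohol = function(x) as.integer(x),
    hypertension = function(x) as.integer(x),
    diabetes = function(x) as.integer(x)
  )
}

#' Severity-ordered integer coding of cohort predictors
#'
#' Recodes the model predictors as equally spaced integer levels in
#' severity order (age and GCS by their grading bins, damaged lobe
#' parietal < occipital < temporal < frontal, Marshall I-VI as 1-6, CRP
#' and IL-8 by their grading bins, binaries as 0/1), so a single logistic
#' coefficient per predictor measures the odds change per one-level
#' increase. Columns without a defined coding are passed through.
#'
#' @param data A cohort data frame.
#' @param predictors Columns to encode.
#' @return Tibble of integer-coded predictors.
#' @export
encode_ordinal <- function(data, predictors) {
  codings <- ordinal_codings()
  out <- purrr::map(predictors, function(p) {
    if (!p %in% names(data)) {
      stop("predictor '", p, "' not present in data", call. = FALSE)
    }
    x <- data[[p]]
    if (p %in% names(codings)) codings[[p]](x) else x
  })
  names(out) <- predictors
  tibble::as_tibble(out)
}

#' Multivariate logistic regression for independent risk factors
#'
#' Fits a maximum-likelihood logistic model of poor outcome on all
#' candidate predictors jointly, with multi-level predictors coded as
#' severity-ordered integers (see [encode_ordinal()]). Reports Wald 95%
#' confidence intervals and p-values on the odds-ratio scale.
#'
#' Perfect separation and non-convergence are explicit errors, never a
#' silently huge odds ratio.
#'
#' @param data A cohort with complete `outcome` labels and no missing
#'   candidate values.
#' @param candidates Predictor columns to include jointly.
#' @return An object of class `eppm_logit`; use [tidy()] for per-predictor
#'   odds ratios and [glance()] for fit summaries.
#' @export
fit_risk_model <- function(data, candidates) {
  if (!"outcome" %in% names(data) || anyNA(data$outcome)) {
    stop("fit_risk_model() needs outcome labels on every record",
         call. = FALSE)
  }
  design <- encode_ordinal(data, candidates)
  if (anyNA(design)) {
    stop("candidates contain missing values", call. = FALSE)
  }
  design$.poor <- as.integer(data$outcome == "poor")
  fit <- stats::glm(.poor ~ ., family = stats::binomial(), data = design)
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter, " IRLS iterations",
         call. = FALSE)
  }
  eta <- abs(stats::predict(fit, type = "link"))
  if (any(abs(stats::coef(fit)[-1]) > 15) || all(eta > 10)) {
    stop("perfect or quasi-perfect separation detected: ",
         "odds ratios are not identifiable", call. = FALSE)
  }
  structure(
    list(fit = fit, candidates = candidates, n = nrow(design)),
    class = "eppm_logit"
  )
}

#' @export
print.eppm_logit <- function(x, ...) {
  cat("<eppm_logit> logistic model of poor outcome on",
      length(x$candidates), "predictors, n =", x$n, "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted risk model into per-predictor odds ratios
#'
#' @param x An `eppm_logit` from [fit_risk_model()].
#' @param ... Unused.
#' @return Tibble: `predictor`, `estimate` (log-odds per level),
#'   `odds_ratio`, `ci_lower`, `ci_upper` (Wald 95%), `p_value`.
#' @export
tidy.eppm_logit <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tibble::tibble(
    predictor = rownames(sm),
    estimate = unname(est),
    odds_ratio = unname(exp(est)),
    ci_lower = unname(exp(est - stats::qnorm(0.975) * se)),
    ci_upper = unname(exp(est + stats::qnorm(0.975) * se)),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
}

#' @rdname tidy.eppm_logit
#' @export
glance.eppm_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = stats::AIC(x$fit),
    converged = x$fit$converged
  )
}

#' Final predictor selection from the two-stage screen
#'
#' Keeps the candidates whose multivariate p-value is below `alpha`,
#' restricted to those that survived the univariate screen, in the stable
#' order of the univariate table.
#'
#' @param univariate Tibble of univariate results (needs `predictor`,
#'   `selected`).
#' @param multivariate Tibble of multivariate results (needs `predictor`,
#'   `p_value`), fitted on the univariate-selected candidates.
#' @param alpha Significance level.
#' @return Character vector of selected predictor names.
#' @export
select_predictors <- function(univariate, multivariate, alpha = 0.05) {
  uni_sel <- univariate$predictor[univariate$selected]
  multi_sel <- multivariate$predictor[multivariate$p_value < alpha]
  intersect(uni_sel, multi_sel)
}

#' Run the full predictor screen on a labelled cohort
#'
#' Stage one compares every candidate between outcome groups: continuous
#' analytes through the normality-gated t / Mann-Whitney branch,
#' categorical and binned predictors (age and GCS by their grading bins)
#' through chi-square / Fisher. Stage two fits a joint multivariate
#' logistic model on the univariate-selected candidates and keeps those
#' with multivariate p < `alpha` as independent risk factors. No
#' multiple-testing correction is applied across the univariate screen.
#'
#' @param data Labelled cohort (every record has an outcome).
#' @param alpha Significance level used at both stages.
#' @param alpha_norm Level of the Shapiro-Wilk normality gate.
#' @param continuous,categorical Candidate columns per type; defaults
#'   cover all serum analytes and all clinical/imaging categoricals.
#' @return An object of class `eppm_screening`: list with tibbles
#'   `univariate` and `multivariate`, and the character vector `selected`.
#' @export
screen_predictors <- function(data, alpha = 0.05, alpha_norm = 0.05,
                              continuous = NULL, categorical = NULL) {
  if (!"outcome" %in% names(data) || anyNA(data$outcome)) {
    stop("screen_predictors() needs outcome labels on every record",
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (is.null(continuous)) {
    continuous <- intersect(c("crp", "il8", extra_lab_names()), names(data))
  }
  if (is.null(categorical)) {
    categorical <- intersect(
      c("age", "sex", "mechanism", "damaged_area", "gcs", "apoe_e4_carrier",
        "marshall", "smoking", "alcohol", "hypertension", "diabetes"),
      names(data)
    )
  }
  poor <- data$outcome == "poor"
  uni_cont <- purrr::map_dfr(continuous, function(p) {
    compare_continuous(data[[p]][poor], data[[p]][!poor],
                       alpha = alpha, alpha_norm = alpha_norm, predictor = p)
  })
  codings <- ordinal_codings()
  cat_levels <- function(p) {
    # bin multi-valued predictors the way the summary tables do
    if (p %in% c("age", "gcs", "crp", "il8")) {
      as.character(codings[[p]](data[[p]]))
    } else if (is.logical(data[[p]])) {
      ifelse(data[[p]], "yes", "no")
    } else {
      as.character(data[[p]])
    }
  }
  uni_cat <- purrr::map_dfr(categorical, function(p) {
    lv <- cat_levels(p)
    tab <- table(outcome = factor(data$outcome, c("poor", "good")), level = lv)
    keep <- colSums(tab) > 0
    compare_categorical(tab[, keep, drop = FALSE],
                        alpha = alpha, predictor = p)
  })
  univariate <- dplyr::bind_rows(uni_cont, uni_cat)

  selected_uni <- univariate$predictor[univariate$selected]
  multivariate <- tibble::tibble(
    predictor = character(), estimate = double(), odds_ratio = double(),
    ci_lower = double(), ci_upper = double(), p_value = double()
  )
  model <- NULL
  if (length(selected_uni) > 0) {
    model <- fit_risk_model(data, selected_uni)
    multivariate <- tidy(model)
  }
  structure(
    list(
      univariate = univariate,
      multivariate = multivariate,
      selected = select_predictors(univariate, multivariate, alpha),
      model = model,
      alpha = alpha
    ),
    class = "eppm_screening"
  )
}

#' @export
print.eppm_screening <- function(x, ...) {
  cat("<eppm_screening> alpha =", x$alpha, "\n")
  cat("univariate-selected:",
      paste(x$univariate$predictor[x$univariate$selected], collapse = ", "),
      "\n")
  cat("independent risk factors:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
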