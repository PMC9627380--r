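#' Synthetic cohort configuration
#'
#' Builds the configuration the synthetic generator draws from: outcome
#' prevalence, per-outcome category probabilities for the informative
#' predictors, per-outcome normal parameters for the serum analytes, the
#' within-bin samplers that turn a sampled age/GCS bin into a concrete
#' integer, and outcome-independent marginals for the non-informative
#' covariates. Defaults come from the published training-cohort summary
#' tables shipped with the package (`cohort_defaults.yaml`), stored as
#' counts so every probability is auditable.
#'
#' Predictors are drawn conditionally independent given the outcome: the
#' source tables publish only per-outcome marginals, so no correlation
#' structure is recoverable. This is a documented limitation of what the
#' generator can emulate.
#'
#' Only the analytes flagged `informative` (CRP and IL-8, the two the
#' source cohort's screen retained) are drawn conditionally on the
#' outcome. The remaining analytes were reported as non-discriminating
#' (p > 0.05) even though per-group means are printed for them, so they
#' are drawn from the outcome-pooled mixture of their two entries: the
#' printed marginal distribution is preserved but no prognostic signal is
#' injected, giving the screening pipeline true negatives to reject.
#'
#' @param path YAML file of default parameters; the shipped file encodes
#'   the published tables.
#' @param poor_prevalence Probability a generated patient has a poor
#'   outcome; default 78/168 from the source cohort.
#' @param categorical,continuous,noninformative Optional overrides,
#'   replacing entries of the corresponding default lists (see the shipped
#'   YAML for the structure).
#' @return An object of class `eppm_cohort_config`.
#' @export
cohort_config <- function(path = system.file("extdata", "cohort_defaults.yaml",
                                             package = "eppm"),
                          poor_prevalence = NULL,
                          categorical = NULL,
                          continuous = NULL,
                          noninformative = NULL) {
  raw <- yaml::read_yaml(path)
  prev <- raw$outcome$poor / (raw$outcome$poor + raw$outcome$good)
  if (!is.null(poor_prevalence)) prev <- poor_prevalence

  cat_cfg <- purrr::map(raw$categorical, function(x) {
    list(
      levels = as.character(x$levels),
      p_poor = x$poor / sum(x$poor),
      p_good = x$good / sum(x$good)
    )
  })
  for (nm in names(categorical)) cat_cfg[[nm]] <- categorical[[nm]]

  cont_cfg <- purrr::imap_dfr(raw$continuous, function(x, nm) {
    poor <- as.numeric(unlist(x$poor))
    good <- as.numeric(unlist(x$good))
    tibble::tibble(
      analyte = nm, unit = x$unit %||% "",
      mean_poor = poor[1], sd_poor = poor[2],
      mean_good = good[1], sd_good = good[2],
      informative = isTRUE(x$informative)
    )
  })
  if (!is.null(continuous)) {
    cont_cfg <- dplyr::rows_update(cont_cfg, tibble::as_tibble(continuous),
                                   by = "analyte")
  }

  noninf <- raw$noninformative
  for (nm in names(noninformative)) noninf[[nm]] <- noninformative[[nm]]

  cfg <- structure(list(
    poor_prevalence = prev,
    categorical = cat_cfg,
    bin_ranges = raw$bin_ranges,
    continuous = cont_cfg,
    noninformative = noninf
  ), class = "eppm_cohort_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  errs <- character()
  if (!(cfg$poor_prevalence > 0 && cfg$poor_prevalence <= 1)) {
    errs <- c(errs, "poor_prevalence must be in (0, 1]")
  }
  for (nm in names(cfg$categorical)) {
    x <- cfg$categorical[[nm]]
    for (side in c("p_poor", "p_good")) {
      p <- x[[side]]
      if (length(p) != length(x$levels)) {
        errs <- c(errs, paste0(nm, ": ", side, " length != number of levels"))
      } else if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
        errs <- c(errs, paste0(nm, ": ", side, " is not a probability vector"))
      }
    }
  }
  if (any(cfg$continuous$sd_poor <= 0) || any(cfg$continuous$sd_good <= 0)) {
    errs <- c(errs, "all analyte SDs must be positive")
  }
  if (length(errs) > 0) {
    stop("invalid cohort config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.eppm_cohort_config <- function(x, ...) {
  cat("<eppm_cohort_config>\n")
  cat("  poor prevalence:", format(x$poor_prevalence, digits = 4), "\n")
  cat("  informative predictors:", paste(names(x$categorical), collapse = ", "),
      "+", nrow(x$continuous), "serum analytes\n")
  cat("  non-informative covariates:",
      paste(names(x$noninformative), collapse = ", "), "\n")
  invisible(x)
}

extra_lab_names <- function() {
  c("hemoglobin", "wbc", "albumin", "aptt", "pt", "inr", "pct", "il6",
    "tb", "db", "alt", "ast", "potassium", "sodium", "calcium",
    "creatinine", "cholesterol")
}

# zero-truncated normal with moment correction: discarding the negative
# tail of N(mean, sd) inflates the realized mean (for CRP 14.20 +/- 5.73
# by ~0.11 mg/L, i.e. ~2 SEs at n = 10,000), so the latent location is
# solved so that the truncated draw has exactly the configured mean. The
# SD distortion is second-order and left uncorrected.
rnorm_nonneg <- function(n, mean, sd) {
  mu <- mean
  if (mean / sd < 5) {
    trunc_mean <- function(m) {
      a <- m / sd
      m + sd * stats::dnorm(a) / stats::pnorm(a)
    }
    mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                         c(mean - 5 * sd, mean), tol = 1e-10)$root
  }
  x <- stats::rnorm(n, mu, sd)
  while (any(neg <- x < 0)) {
    x[neg] <- stats::rnorm(sum(neg), mu, sd)
  }
  x
}

sample_level <- function(n, levels, prob) {
  if (n == 0) return(character())
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

# uniform integer draw within the sampled bin
sample_within_bins <- function(bins, ranges) {
  vapply(bins, function(b) {
    r <- ranges[[b]]
    sample(seq.int(r[1], r[2]), 1L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic TBI cohort
#'
#' Draws `n` patient records whose predictors, conditional on outcome,
#' follow the configured category probabilities and normal analyte
#' summaries: the outcome is Bernoulli(poor prevalence); each categorical
#' predictor is drawn from its outcome-conditional vector (age and GCS get
#' a concrete integer uniform within the sampled bin); each analyte from
#' the outcome-conditional normal truncated at 0; non-informative
#' covariates from outcome-independent marginals. Deterministic for a
#' fixed seed, and every record passes [validate_cohort()].
#'
#' `generate_null_cohort()` keeps the same marginal structure but severs
#' the predictor-outcome link: predictors are drawn conditional on an
#' independent phantom outcome, i.e. from the outcome-pooled mixture, so
#' no predictor carries signal. Useful for type-I-error and null-AUC
#' checks.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @param config An `eppm_cohort_config`.
#' @return A tibble of patient records with attributes `seed` and
#'   `config_hash` for provenance.
#' @examples
#' cohort <- generate_cohort(50, seed = 7)
#' dplyr::count(cohort, outcome)
#' @export
generate_cohort <- function(n, seed = 1L, config = cohort_config()) {
  generate_impl(n, seed, config, null_signal = FALSE)
}

#' @rdname generate_cohort
#' @export
generate_null_cohort <- function(n, seed = 1L, config = cohort_config()) {
  generate_impl(n, seed, config, null_signal = TRUE)
}

generate_impl <- function(n, seed, config, null_signal) {
  validate_config(config)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("invalid cohort config: n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  with_local_seed(seed, {
    outcome <- ifelse(stats::runif(n) < config$poor_prevalence, "poor", "good")
    # under the null, predictors follow the outcome-pooled mixture:
    # condition them on an independent phantom outcome instead
    driver <- if (null_signal) {
      ifelse(stats::runif(n) < config$poor_prevalence, "poor", "good")
    } else {
      outcome
    }
    is_poor <- driver == "poor"

    draw_cat <- function(nm) {
      x <- config$categorical[[nm]]
      out <- character(n)
      out[is_poor] <- sample_level(sum(is_poor), x$levels, x$p_poor)
      out[!is_poor] <- sample_level(sum(!is_poor), x$levels, x$p_good)
      out
    }
    age_bin <- draw_cat("age_bin")
    gcs_bin <- draw_cat("gcs_bin")
    rec <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = sample_within_bins(age_bin, config$bin_ranges$age_bin),
      gcs = sample_within_bins(gcs_bin, config$bin_ranges$gcs_bin),
      damaged_area = draw_cat("damaged_area"),
      apoe_e4_carrier = draw_cat("apoe_e4_carrier") == "yes",
      marshall = draw_cat("marshall")
    )
    for (i in seq_len(nrow(config$continuous))) {
      row <- config$continuous[i, ]
      # non-discriminating analytes follow the outcome-pooled mixture: an
      # independent phantom outcome picks the component, so the marginal
      # distribution is kept but the analyte carries no prognostic signal
      grp <- if (row$informative) {
        is_poor
      } else {
        stats::runif(n) < config$poor_prevalence
      }
      v <- numeric(n)
      v[grp] <- rnorm_nonneg(sum(grp), row$mean_poor, row$sd_poor)
      v[!grp] <- rnorm_nonneg(sum(!grp), row$mean_good, row$sd_good)
      rec[[row$analyte]] <- v
    }
    ni <- config$noninformative
    rec$sex <- sample_level(n, ni$sex$levels, ni$sex$counts)
    rec$mechanism <- sample_level(n, ni$mechanism$levels, ni$mechanism$counts)
    for (flag in c("smoking", "alcohol", "hypertension", "diabetes")) {
      p <- ni[[flag]]$count_yes / ni[[flag]]$n_total
      rec[[flag]] <- stats::runif(n) < p
    }
    rec$outcome <- outcome
    rec <- dplyr::relocate(rec, "patient_id", "age", "sex", "mechanism",
                           "damaged_area", "gcs", "apoe_e4_carrier",
                           "crp", "il8", "marshall")
    attr(rec, "seed") <- seed
    attr(rec, "config_hash") <- rlang::hash(config)
    rec
  })
}

#' Summarise a cohort in the layout of the source tables
#'
#' Produces per-outcome summaries shaped for eyeball comparison against
#' the published tables: mean +/- SD per serum analyte, and per-outcome
#' category counts for the informative predictors (age and GCS are binned
#' with the configured bin ranges).
#'
#' @param data A cohort with outcome labels.
#' @param config Configuration providing the age/GCS bin definitions.
#' @return A list with tibbles `outcome` (class counts), `continuous`
#'   (analyte, mean/SD by outcome; SD is `NA` for a single patient), and
#'   `categorical` (predictor, level, counts by outcome).
#' @export
summarize_cohort <- function(data, config = cohort_config()) {
  if (!"outcome" %in% names(data) || anyNA(data$outcome)) {
    stop("summarize_cohort() needs outcome labels on every record",
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  bin_of <- function(x, ranges) {
    labs <- names(ranges)
    out <- rep(NA_character_, length(x))
    for (lab in labs) {
      r <- ranges[[lab]]
      out[x >= r[1] & x <= r[2]] <- lab
    }
    out
  }
  data$age_bin <- bin_of(data$age, config$bin_ranges$age_bin)
  data$gcs_bin <- bin_of(data$gcs, config$bin_ranges$gcs_bin)
  data$apoe_e4_carrier <- ifelse(data$apoe_e4_carrier, "yes", "no")

  analytes <- intersect(config$continuous$analyte, names(data))
  continuous <- data |>
    dplyr::select(dplyr::all_of(c("outcome", analytes))) |>
    tidyr::pivot_longer(-"outcome", names_to = "analyte") |>
    dplyr::group_by(.data$analyte, .data$outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "outcome",
                       values_from = c("n", "mean", "sd")) |>
    dplyr::arrange(match(.data$analyte, config$continuous$analyte))

  cat_preds <- names(config$categorical)
  categorical <- purrr::map_dfr(cat_preds, function(nm) {
    lv <- config$categorical[[nm]]$levels
    data |>
      dplyr::count(.data$outcome, level = .data[[nm]]) |>
      tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                         values_fill = 0L) |>
      dplyr::mutate(predictor = nm, .before = 1) |>
      dplyr::arrange(match(.data$level, lv))
  })
  for (col in c("poor", "good")) {
    if (!col %in% names(categorical)) categorical[[col]] <- 0L
  }

  list(
    outcome = dplyr::count(data, .data$outcome),
    continuous = continuous,
    categorical = categorical
  )
}

#' Rebuild a generator configuration from an empirical cohort summary
#'
#' Closes the moment-matching loop: the summary of a generated (or real)
#' cohort becomes the parameter source for a new configuration, so
#' re-generation reproduces the summary within sampling error.
#'
#' @param summary Output of [summarize_cohort()].
#' @param base Configuration supplying structure (levels, bin ranges) for
#'   entries the summary does not cover.
#' @return An `eppm_cohort_config`.
#' @export
cohort_config_from_summary <- function(summary, base = cohort_config()) {
  cfg <- base
  n_poor <- summary$outcome$n[summary$outcome$outcome == "poor"]
  n_good <- summary$outcome$n[summary$outcome$outcome == "good"]
  cfg$poor_prevalence <- n_poor / (n_poor + n_good)
  for (nm in names(cfg$categorical)) {
    tab <- summary$categorical[summary$categorical$predictor == nm, ]
    lv <- cfg$categorical[[nm]]$levels
    cnt <- function(col) {
      v <- tab[[col]][match(lv, tab$level)]
      v[is.na(v)] <- 0
      v
    }
    poor <- cnt("poor"); good <- cnt("good")
    if (sum(poor) > 0 && sum(good) > 0) {
      cfg$categorical[[nm]]$p_poor <- poor / sum(poor)
      cfg$categorical[[nm]]$p_good <- good / sum(good)
    }
  }
  cont <- summary$continuous
  for (i in seq_len(nrow(cont))) {
    j <- match(cont$analyte[i], cfg$continuous$analyte)
    if (!is.na(j)) {
      cfg$continuous$mean_poor[j] <- cont$mean_poor[i]
      cfg$continuous$sd_poor[j] <- cont$sd_poor[i]
      cfg$continuous$mean_good[j] <- cont$mean_good[i]
      cfg$continuous$sd_good[j] <- cont$sd_good[i]
    }
  }
  validate_config(cfg)
  cfg
}
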