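#' Score a cohort with the EPPM grading rules
#'
#' Converts each requested predictor of every patient into points and sums
#' them into the EPPM total. With the default rules and all seven
#' predictors the total lies in \[10, 33\]. If `threshold` is supplied, a
#' `predicted` column classifies each patient (`"poor"` iff
#' `total > threshold`).
#'
#' Missing values in a requested predictor are an error, never imputed.
#'
#' @param data A data frame of patient records; must contain one column per
#'   requested predictor (see [default_rules()] for names and units).
#' @param rules An `eppm_rules` object.
#' @param predictors Character vector of predictors to score. Defaults to
#'   all predictors defined by `rules` (the seven-predictor model).
#' @param threshold Optional decision threshold (the published model uses
#'   23.5); if given, adds a `predicted` factor column.
#' @return A tibble: the input columns, one `pts_<predictor>` column per
#'   scored predictor, `total`, and optionally `predicted`.
#' @examples
#' # the grading-rules worked example: six predictors sum to 19
#' patient <- tibble::tibble(
#'   age = 46, damaged_area = "temporal", gcs = 8, apoe_e4_carrier = TRUE,
#'   crp = 14.2, il8 = 15.2, marshall = "III"
#' )
#' score_cohort(patient, predictors = setdiff(names(default_rules()), "gcs"))
#' @export
score_cohort <- function(data, rules = default_rules(),
                         predictors = names(rules), threshold = NULL) {
  stopifnot(is.data.frame(data))
  unknown <- setdiff(predictors, names(rules))
  if (length(unknown) > 0) {
    stop("predictors not defined by the rules: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks predictor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  pts <- purrr::map(predictors, function(p) {
    grade_predictor(p, out[[p]], rules)
  })
  names(pts) <- paste0("pts_", predictors)
  out <- dplyr::bind_cols(out, tibble::as_tibble(pts))
  out$total <- as.integer(Reduce(`+`, pts))
  if (!is.null(threshold)) {
    out$predicted <- classify_score(out$total, threshold)
  }
  out
}

#' Classify an EPPM total score against a decision threshold
#'
#' A patient is predicted to have a poor early prognosis iff the total
#' score is strictly greater than the threshold. The published threshold
#' is 23.5, so integer totals >= 24 are classified poor.
#'
#' @param total Integer total scores.
#' @param threshold Decision threshold; must lie strictly inside the
#'   achievable score range so both classes are reachable.
#' @param rules Rules used only to validate the threshold against the
#'   achievable range.
#' @return Factor with levels `poor`, `good`.
#' @examples
#' classify_score(c(19, 24, 33), 23.5)
#' @export
classify_score <- function(total, threshold = 23.5, rules = default_rules()) {
  rng <- score_range(rules)
  if (!(threshold > rng[["min"]] && threshold < rng[["max"]])) {
    stop("threshold ", threshold, " must lie strictly inside the achievable ",
         "score range [", rng[["min"]], ", ", rng[["max"]], "]", call. = FALSE)
  }
  factor(ifelse(total > threshold, "poor", "good"), levels = c("poor", "good"))
}
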