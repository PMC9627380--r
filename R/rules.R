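#' EPPM grading rules
#'
#' The EPPM converts each of seven admission predictors into an integer
#' number of points; the patient's score is the sum. Rules are data, not
#' code: they live in a YAML file mapping each predictor either to ordered
#' numeric bins (`min`/`max`/`points`) or to a category -> points table, so
#' alternative point schemes can be evaluated without code changes.
#' `default_rules()` loads the scheme shipped with the package:
#'
#' | predictor         | bins -> points                                   |
#' |-------------------|--------------------------------------------------|
#' | `age` (years)     | <=45 -> 4, 46-59 -> 5, >=60 -> 6                 |
#' | `damaged_area`    | parietal/occipital -> 2, temporal -> 3, frontal -> 4 |
#' | `gcs`             | 13-15 -> 1, 9-12 -> 3, <=8 -> 6                  |
#' | `apoe_e4_carrier` | no -> 0, yes -> 2                                |
#' | `crp` (mg/L)      | <10 -> 2, 10-15 -> 3, >=15 -> 5                  |
#' | `il8` (pg/mL)     | <10 -> 0, 10-20 -> 2, >=20 -> 4                  |
#' | `marshall`        | I/II -> 1, III/IV -> 4, V/VI -> 6                |
#'
#' Numeric bins are half-open `[min, max)` except the top bin, which is
#' closed at the domain maximum; at abutting edges the more severe
#' category wins (CRP 15 scores 5, IL-8 20 scores 4, age 60 scores 6).
#'
#' @param path Path to a rules YAML file.
#' @return An object of class `eppm_rules`: a named list with one entry per
#'   predictor, each carrying `type` (`"numeric"` or `"categorical"`) and
#'   either a `bins` tibble or a named `levels` vector of points.
#' @examples
#' rules <- default_rules()
#' grade_predictor("age", 46, rules)
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    stop("rules file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  rules <- purrr::imap(raw, function(spec, name) {
    type <- spec$type
    if (identical(type, "numeric")) {
      bins <- purrr::map_dfr(spec$bins, tibble::as_tibble)
      bins <- dplyr::arrange(bins, .data$min)
      dom <- as.numeric(spec$domain)
      list(type = "numeric", domain = dom, bins = bins)
    } else if (identical(type, "categorical")) {
      lv <- unlist(spec$levels)
      list(type = "categorical", levels = lv)
    } else {
      stop("predictor '", name, "': unknown type '", type, "'", call. = FALSE)
    }
  })
  structure(rules, class = "eppm_rules")
}

#' @rdname read_rules
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "grading_rules.yaml", package = "eppm"))
}

#' @export
print.eppm_rules <- function(x, ...) {
  cat("<eppm_rules> grading rules for", length(x), "predictors:\n")
  for (nm in names(x)) {
    r <- x[[nm]]
    if (r$type == "numeric") {
      lab <- paste0("[", r$bins$min, ",", r$bins$max, ")->", r$bins$points,
                    collapse = " ")
    } else {
      lab <- paste0(names(r$levels), "->", r$levels, collapse = " ")
    }
    cat(" ", format(nm, width = 16), lab, "\n")
  }
  invisible(x)
}

#' Score range achievable under a set of grading rules
#'
#' @param rules An `eppm_rules` object.
#' @return Integer vector `c(min, max)`: the least and most severe totals
#'   when every predictor is scored (10 and 33 under the default rules).
#' @export
score_range <- function(rules = default_rules()) {
  per <- purrr::map(rules, function(r) {
    pts <- if (r$type == "numeric") r$bins$points else r$levels
    range(pts)
  })
  c(
    min = sum(purrr::map_dbl(per, 1)),
    max = sum(purrr::map_dbl(per, 2))
  )
}

#' Grade a single predictor value
#'
#' Maps one predictor value (vectorised) to its point contribution under a
#' set of grading rules.
#'
#' @param predictor Predictor name (one of `names(rules)`).
#' @param value Numeric values for numeric predictors; character/logical for
#'   categorical ones (`apoe_e4_carrier` accepts `TRUE`/`FALSE`, `"yes"`/`"no"`).
#' @param rules An `eppm_rules` object.
#' @return Integer vector of points, same length as `value`.
#' @examples
#' grade_predictor("age", 46)       # 5
#' grade_predictor("marshall", "III") # 4
#' @export
grade_predictor <- function(predictor, value, rules = default_rules()) {
  if (!predictor %in% names(rules)) {
    stop("unknown predictor '", predictor, "'; rules define: ",
         paste(names(rules), collapse = ", "), call. = FALSE)
  }
  r <- rules[[predictor]]
  if (r$type == "numeric") {
    value <- as.numeric(value)
    if (anyNA(value)) {
      stop("predictor '", predictor, "': missing value", call. = FALSE)
    }
    dom <- r$domain
    bad <- value < dom[1] | value > dom[2]
    if (any(bad)) {
      stop("predictor '", predictor, "': value ", value[bad][1],
           " outside domain [", dom[1], ", ", dom[2], "]", call. = FALSE)
    }
    # half-open [min, max) bins; findInterval on left edges puts a value
    # equal to an upper edge into the next (more severe) bin, and the
    # domain maximum stays in the top bin
    idx <- findInterval(value, r$bins$min)
    as.integer(r$bins$points[idx])
  } else {
    value <- normalise_level(predictor, value)
    known <- names(r$levels)
    bad <- !value %in% known
    if (any(bad)) {
      stop("predictor '", predictor, "': unknown level '", value[bad][1],
           "' (expected one of ", paste(known, collapse = ", "), ")",
           call. = FALSE)
    }
    as.integer(r$levels[value])
  }
}

# canonicalise categorical inputs: logicals/"TRUE" to yes/no, case folding
normalise_level <- function(predictor, value) {
  if (is.logical(value)) {
    if (anyNA(value)) {
      stop("predictor '", predictor, "': missing value", call. = FALSE)
    }
    return(ifelse(value, "yes", "no"))
  }
  value <- as.character(value)
  if (anyNA(value)) {
    stop("predictor '", predictor, "': missing value", call. = FALSE)
  }
  if (predictor == "apoe_e4_carrier") tolower(value)
  else if (predictor == "damaged_area") tolower(value)
  else value
}
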