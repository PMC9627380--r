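#' @importFrom rlang .data
NULL

# canonical cohort columns; outcome and comorbidity flags are optional
mandatory_cols <- c(
  "patient_id", "age", "sex", "mechanism", "damaged_area", "gcs",
  "apoe_e4_carrier", "crp", "il8", "marshall"
)
marshall_levels <- c("I", "II", "III", "IV", "V", "VI")
sex_levels <- c("male", "female")
mechanism_levels <- c("traffic", "striking", "fall", "other")
area_levels <- c("frontal", "temporal", "parietal", "occipital")
outcome_levels <- c("poor", "good")
comorbidity_cols <- c("smoking", "alcohol", "hypertension", "diabetes")

# run an expression under a temporary RNG state; restores the caller's seed
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Validate a cohort of patient records
#'
#' Checks every record against the cohort invariants: age within the
#' 15-75-year inclusion window, GCS in 3-15, non-negative CRP and IL-8,
#' Marshall class I-VI, recognised categorical levels, and unique patient
#' identifiers. Violations are collected and reported, never silently
#' dropped.
#'
#' @param data A data frame of patient records in canonical columns.
#' @return A tibble of problems with columns `row`, `column`, `reason`;
#'   zero rows means the cohort is valid.
#' @export
validate_cohort <- function(data) {
  probs <- list()
  note <- function(rows, column, reason) {
    rows <- which(rows)
    if (length(rows) > 0) {
      probs[[length(probs) + 1]] <<- tibble::tibble(
        row = rows, column = column, reason = reason
      )
    }
  }
  num_bad <- function(x, lo, hi) {
    is.na(x) | x < lo | x > hi
  }
  if (nrow(data) > 0) {
    note(num_bad(data$age, 15, 75), "age", "age outside 15-75")
    note(num_bad(data$gcs, 3, 15), "gcs", "GCS outside 3-15")
    note(is.na(data$crp) | data$crp < 0, "crp", "CRP missing or negative")
    note(is.na(data$il8) | data$il8 < 0, "il8", "IL-8 missing or negative")
    note(!data$marshall %in% marshall_levels, "marshall",
         "Marshall class not I-VI")
    note(!data$sex %in% sex_levels, "sex", "sex not male/female")
    note(!data$mechanism %in% mechanism_levels, "mechanism",
         "unrecognised injury mechanism")
    note(!data$damaged_area %in% area_levels, "damaged_area",
         "unrecognised damaged lobe")
    note(is.na(data$apoe_e4_carrier), "apoe_e4_carrier",
         "carrier status missing")
    if ("outcome" %in% names(data)) {
      note(!is.na(data$outcome) & !data$outcome %in% outcome_levels,
           "outcome", "outcome not poor/good")
    }
    note(duplicated(data$patient_id), "patient_id", "duplicate patient_id")
  }
  if (length(probs) == 0) {
    tibble::tibble(row = integer(), column = character(), reason = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  }
}

#' Read a patient cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered cohort file. Booleans are
#' written `yes`/`no` and Marshall classes as Roman numerals I-VI, matching
#' the notation clinicians audit against. Nonstandard column names are
#' resolved through `schema`, a named character vector (or YAML file of
#' one) mapping canonical names to the file's headers.
#'
#' Rows violating the record invariants are kept and reported in the
#' `problems` attribute (a tibble of `row`, `column`, `reason`); with
#' `strict = TRUE` any problem aborts the read.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector `c(canonical = "file_col")`
#'   or path to a YAML file containing such a mapping.
#' @param strict Abort if any record fails validation?
#' @return A tibble of patient records with a `problems` attribute.
#' @export
read_cohort <- function(path, schema = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema) &&
      grepl("\\.ya?ml$", schema)) {
    schema <- unlist(yaml::read_yaml(schema))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(schema)) {
    have <- schema[schema %in% names(raw)]
    raw <- dplyr::rename(raw, !!!have)
  }
  missing_cols <- setdiff(mandatory_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_problems <- list()
  parse_num <- function(x, column) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      parse_problems[[length(parse_problems) + 1]] <<- tibble::tibble(
        row = bad, column = column,
        reason = paste0("unparseable value '", x[bad], "'")
      )
    }
    out
  }
  parse_yesno <- function(x, column) {
    lx <- tolower(x)
    out <- dplyr::case_when(
      lx %in% c("yes", "true", "1") ~ TRUE,
      lx %in% c("no", "false", "0") ~ FALSE,
      .default = NA
    )
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      parse_problems[[length(parse_problems) + 1]] <<- tibble::tibble(
        row = bad, column = column,
        reason = paste0("expected yes/no, got '", x[bad], "'")
      )
    }
    out
  }
  data <- raw
  for (col in intersect(c("age", "gcs", "crp", "il8", extra_lab_names()),
                        names(data))) {
    data[[col]] <- parse_num(data[[col]], col)
  }
  for (col in intersect(c("apoe_e4_carrier", comorbidity_cols), names(data))) {
    data[[col]] <- parse_yesno(data[[col]], col)
  }
  if ("outcome" %in% names(data)) {
    data$outcome <- dplyr::na_if(data$outcome, "")
  }
  data <- tibble::as_tibble(data)
  problems <- dplyr::bind_rows(
    dplyr::bind_rows(parse_problems),
    validate_cohort(data)
  )
  problems <- if (nrow(problems) > 0) dplyr::arrange(problems, .data$row) else {
    tibble::tibble(row = integer(), column = character(), reason = character())
  }
  if (strict && nrow(problems) > 0) {
    stop("cohort failed validation: ", nrow(problems), " problem(s), first: row ",
         problems$row[1], " (", problems$column[1], ") ", problems$reason[1],
         call. = FALSE)
  }
  attr(data, "problems") <- problems
  data
}

#' Write a patient cohort to CSV
#'
#' Serialises with the same dialect [read_cohort()] expects: booleans as
#' `yes`/`no`, Marshall class as Roman numerals, missing outcomes as empty
#' cells. Reading the file back reproduces all fields.
#'
#' @param data A data frame of patient records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- tibble::as_tibble(data)
  for (col in intersect(c("apoe_e4_carrier", comorbidity_cols), names(out))) {
    out[[col]] <- ifelse(out[[col]], "yes", "no")
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Randomly split a cohort into the study's four sets
#'
#' Draws disjoint subsets of the requested sizes without replacement,
#' mirroring the study design of a training set split ~1:2 into a
#' screening part and a model-training part, plus validation and testing
#' sets. Deterministic for a fixed seed.
#'
#' @param data A data frame of patient records.
#' @param sizes Four non-negative integers; defaults to the published
#'   168/300/100/64 split of a 632-patient cohort.
#' @param seed Integer seed for the assignment.
#' @return Named list of tibbles `part1`, `part2`, `validation`, `testing`;
#'   any rows left over are in the `remainder` attribute.
#' @export
split_cohort <- function(data, sizes = c(168, 300, 100, 64), seed = 1L) {
  stopifnot(length(sizes) == 4, all(sizes >= 0))
  n <- nrow(data)
  if (sum(sizes) > n) {
    stop("requested sizes sum to ", sum(sizes), " but the cohort has only ",
         n, " records", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-4] + 1L)
  sets <- purrr::map2(starts, ends, function(a, b) {
    idx <- if (b >= a) perm[a:b] else integer()
    tibble::as_tibble(data[sort(idx), , drop = FALSE])
  })
  names(sets) <- c("part1", "part2", "validation", "testing")
  rest <- if (ends[4] < n) perm[(ends[4] + 1L):n] else integer()
  attr(sets, "remainder") <- tibble::as_tibble(data[sort(rest), , drop = FALSE])
  sets
}
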