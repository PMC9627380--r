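# the worked-example patient from the published grading-rules table
example_patient <- function() {
  tibble::tibble(
    patient_id = "EX1", age = 46, sex = "male", mechanism = "traffic",
    damaged_area = "temporal", gcs = 8, apoe_e4_carrier = TRUE,
    crp = 14.2, il8 = 15.2, marshall = "III"
  )
}

# random valid patients drawn uniformly over each predictor's domain
# (independent of the synthetic-cohort generator on purpose: exercises the
# whole scoring domain, not just table-realistic regions)
random_patients <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = sprintf("R%05d", seq_len(n)),
    age = sample(15:75, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    mechanism = sample(c("traffic", "striking", "fall", "other"), n, TRUE),
    damaged_area = sample(c("frontal", "temporal", "parietal", "occipital"),
                          n, TRUE),
    gcs = sample(3:15, n, replace = TRUE),
    apoe_e4_carrier = sample(c(TRUE, FALSE), n, replace = TRUE),
    crp = stats::runif(n, 0, 40),
    il8 = stats::runif(n, 0, 40),
    marshall = sample(c("I", "II", "III", "IV", "V", "VI"), n, TRUE)
  ))
}

# brute-force tie-adjusted concordance: (concordant + 0.5 * tied) pairs
pair_counting_auc <- function(scores, labels) {
  poor <- scores[labels == "poor"]
  good <- scores[labels == "good"]
  total <- 0
  for (p in poor) {
    total <- total + sum(p > good) + 0.5 * sum(p == good)
  }
  total / (length(poor) * length(good))
}

# from-scratch Pearson chi-square (no continuity correction)
pearson_chisq <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
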