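# Default synthetic-cohort parameters: outcome-conditional category counts
# and laboratory mean/SD summaries of a 168-patient TBI training cohort
# (78 poor / 90 good early prognoses). Counts are stored, not proportions,
# so the provenance of every probability is auditable.
outcome:
  poor: 78
  good: 90

# Outcome-conditional category counts for the informative predictors.
categorical:
  age_bin:
    levels: ["<=45", "46-59", ">=60"]
    poor: [24, 20, 34]
    good: [44, 31, 15]
  damaged_area:
    levels: [frontal, temporal, parietal, occipital]
    poor: [47, 19, 5, 7]
    good: [31, 24, 17, 18]
  gcs_bin:
    levels: ["13-15", "9-12", "<=8"]
    poor: [8, 36, 34]
    good: [22, 53, 15]
  apoe_e4_carrier:
    levels: ["yes", "no"]
    poor: [37, 41]
    good: [28, 62]
  marshall:
    levels: [I, II, III, IV, V, VI]
    poor: [3, 8, 15, 13, 20, 19]
    good: [15, 24, 23, 14, 8, 6]

# How a concrete value is drawn once a bin is sampled (uniform integers).
bin_ranges:
  age_bin:
    "<=45": [15, 45]
    "46-59": [46, 59]
    ">=60": [60, 75]
  gcs_bin:
    "13-15": [13, 15]
    "9-12": [9, 12]
    "<=8": [3, 8]

# Normal parameters (mean, sd) for the serum analytes by prognosis group;
# all truncated at 0. Only analytes marked informative are drawn
# conditionally on the patient's outcome; the rest — which the source
# cohort reported as non-discriminating (p > 0.05) despite the printed
# group means — are drawn from the outcome-pooled mixture of the two
# entries, so they carry no prognostic signal but keep the printed
# marginal distribution.
continuous:
  hemoglobin:  {unit: "g/L",      poor: [112.00, 27.20], good: [116.70, 18.51]}
  wbc:         {unit: "10^9/L",   poor: [11.63, 3.61],   good: [12.05, 3.72]}
  albumin:     {unit: "g/L",      poor: [37.83, 5.81],   good: [35.91, 6.40]}
  aptt:        {unit: "s",        poor: [38.11, 6.31],   good: [36.24, 7.26]}
  pt:          {unit: "s",        poor: [18.46, 4.12],   good: [18.91, 5.11]}
  inr:         {unit: "",         poor: [1.42, 0.31],    good: [1.32, 0.40]}
  crp:         {unit: "mg/L",     poor: [14.20, 5.73],   good: [11.97, 3.84], informative: true}
  pct:         {unit: "ng/L",     poor: [0.62, 0.41],    good: [0.59, 0.36]}
  il6:         {unit: "pg/mL",    poor: [7.53, 2.35],    good: [6.97, 1.29]}
  il8:         {unit: "pg/mL",    poor: [23.68, 5.35],   good: [21.59, 4.10], informative: true}
  tb:          {unit: "umol/L",   poor: [5.9, 1.6],      good: [6.7, 1.8]}
  db:          {unit: "umol/L",   poor: [3.5, 1.6],      good: [3.4, 1.3]}
  alt:         {unit: "U/L",      poor: [30.1, 15.3],    good: [32.4, 18.3]}
  ast:         {unit: "U/L",      poor: [33.2, 16.5],    good: [34.5, 11.2]}
  potassium:   {unit: "mmol/L",   poor: [3.8, 1.2],      good: [4.0, 1.1]}
  sodium:      {unit: "mmol/L",   poor: [141, 13.5],     good: [139, 15.2]}
  calcium:     {unit: "mmol/L",   poor: [2.34, 0.36],    good: [2.26, 0.41]}
  creatinine:  {unit: "umol/L",   poor: [80.12, 17.46],  good: [71.58, 13.05]}
  cholesterol: {unit: "mmol/L",   poor: [4.07, 1.85],    good: [4.28, 2.32]}

# Covariates with no prognostic signal, drawn independently of outcome
# from the cohort marginals (counts out of 168): the screening pipeline
# needs true negatives to reject.
noninformative:
  sex:
    levels: [male, female]
    counts: [91, 77]
  mechanism:
    levels: [traffic, striking, fall, other]
    counts: [38, 35, 53, 42]
  smoking:    {count_yes: 75, n_total: 168}
  alcohol:    {count_yes: 89, n_total: 168}
  hypertension: {count_yes: 78, n_total: 168}
  diabetes:   {count_yes: 70, n_total: 168}
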