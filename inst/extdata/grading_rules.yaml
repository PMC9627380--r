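# Default EPPM grading rules: per-predictor bins -> integer points.
# Numeric bins are half-open [min, max); the top bin is closed at the
# predictor's domain maximum. Abutting edges therefore take the points of
# the upper (more severe) category: CRP 15 -> 5, IL-8 20 -> 4, age 60 -> 6.
age:
  type: numeric
  domain: [15, 75]
  bins:
    - {min: 15, max: 46, points: 4, label: "<=45"}
    - {min: 46, max: 60, points: 5, label: "46-59"}
    - {min: 60, max: 75, points: 6, label: ">=60"}
damaged_area:
  type: categorical
  levels:
    parietal: 2
    occipital: 2
    temporal: 3
    frontal: 4
gcs:
  type: numeric
  domain: [3, 15]
  bins:
    - {min: 3, max: 9, points: 6, label: "<=8"}
    - {min: 9, max: 13, points: 3, label: "9-12"}
    - {min: 13, max: 15, points: 1, label: "13-15"}
apoe_e4_carrier:
  type: categorical
  levels:
    "no": 0
    "yes": 2
crp:
  type: numeric
  domain: [0, .inf]
  bins:
    - {min: 0, max: 10, points: 2, label: "<10"}
    - {min: 10, max: 15, points: 3, label: "10-15"}
    - {min: 15, max: .inf, points: 5, label: ">=15"}
il8:
  type: numeric
  domain: [0, .inf]
  bins:
    - {min: 0, max: 10, points: 0, label: "<10"}
    - {min: 10, max: 20, points: 2, label: "10-20"}
    - {min: 20, max: .inf, points: 4, label: ">=20"}
marshall:
  type: categorical
  levels:
    I: 1
    II: 1
    III: 4
    IV: 4
    V: 6
    VI: 6
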