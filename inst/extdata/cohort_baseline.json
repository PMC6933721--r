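{
  "description": "Published baseline characteristics of the placental methylation cohort (41 GDM cases, 41 controls): mean (SD) per group for continuous variables, per-group level counts for categorical variables, and the published p-values.",
  "continuous": {
    "maternal_age": {
      "unit": "years",
      "cases": {"mean": 33.171, "sd": 4.652, "n": 41},
      "controls": {"mean": 33.487, "sd": 4.853, "n": 41},
      "published_p": 0.7635
    },
    "gestational_age": {
      "unit": "weeks",
      "cases": {"mean": 39.077, "sd": 0.932, "n": 41},
      "controls": {"mean": 39.206, "sd": 1.047, "n": 41},
      "published_p": 0.5576
    }
  },
  "categorical": {
    "smoking": {
      "levels": ["no", "yes"],
      "cases": [38, 3],
      "controls": [38, 3],
      "published_p": 1
    },
    "infant_sex": {
      "levels": ["male", "female"],
      "cases": [20, 21],
      "controls": [21, 20],
      "published_p": 1
    },
    "conception": {
      "levels": ["spontaneous_planned", "spontaneous_unplanned", "ovulation_induction", "ivf"],
      "cases": [24, 12, 2, 3],
      "controls": [24, 12, 2, 3],
      "published_p": 1
    }
  }
}
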