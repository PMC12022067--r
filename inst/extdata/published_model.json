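{
  "decision_cutoff": 0.5,
  "priors": {
    "n_overall": 234,
    "decliners_overall": 58,
    "brackets": [
      {"lo": 30, "hi": 40, "n": 9, "decliners": 3},
      {"lo": 40, "hi": 45, "n": 7, "decliners": 2},
      {"lo": 45, "hi": 50, "n": 31, "decliners": 3},
      {"lo": 50, "hi": 55, "n": 27, "decliners": 3},
      {"lo": 55, "hi": 60, "n": 41, "decliners": 8},
      {"lo": 60, "hi": 65, "n": 43, "decliners": 10},
      {"lo": 65, "hi": 70, "n": 40, "decliners": 16},
      {"lo": 70, "hi": 75, "n": 19, "decliners": 6},
      {"lo": 75, "hi": 100, "n": 11, "decliners": 7}
    ]
  },
  "features": [
    {
      "name": "stroke",
      "description": "History of ischemic or hemorrhagic stroke",
      "lr_pos": "Inf",
      "lr_neg": 0.94,
      "role": "risk",
      "development_counts": {"tp": 3, "fn": 46, "fp": 0, "tn": 137},
      "validation_counts_note": "one affected subject in the validation cohort, also a decliner"
    },
    {
      "name": "fainting",
      "description": "Fainted in the past 6 months (SCOPA-AUT item 16)",
      "lr_pos": 2.8,
      "lr_neg": 0.97,
      "role": "risk",
      "development_counts": {"tp": 2, "fn": 47, "fp": 2, "tn": 135}
    },
    {
      "name": "vocalization",
      "description": "Speaking, shouting, swearing or laughing loudly during dreams (RBDSQ item 6.1)",
      "lr_pos": 2.7,
      "lr_neg": 0.56,
      "role": "risk",
      "development_counts": {"tp": 27, "fn": 22, "fp": 28, "tn": 109}
    }
  ],
  "provenance": {
    "package": "cognilr",
    "note": "Published four-question model: age-of-onset bracket priors pooled over the development and validation cohorts; likelihood ratios estimated on the development cohort. None of the three features qualifies on the protective side (all LR- >= 0.5), so absence contributes no evidence."
  }
}
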