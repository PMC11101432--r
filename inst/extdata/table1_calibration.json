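{
  "version": "1.0",
  "notes": "Default calibration for the synthetic cohort generator. 'counts' is the published 5x4 cross-tabulation of molecular truth (rows: LAR, IM, BL1, M, UNC) against the classified subtype (columns: LAR, LP, LI, LD) over 317 cases; priors and truth-conditional column probabilities are derived from it at run time. Hazard ratios are relative to the LP group; the three LD values are the published OS/RFS/DFS estimates, the LAR and LI values are interpolated stated-world choices (see the methods vignette). Hazards are per month.",
  "counts": {
    "LAR": [34, 1, 4, 6],
    "IM":  [10, 38, 7, 7],
    "BL1": [1, 17, 23, 21],
    "M":   [13, 1, 10, 56],
    "UNC": [13, 16, 15, 24]
  },
  "column_profiles": {
    "LAR": {
      "ar_percent": [70, 80, 90, 100],
      "ar_intensity": ["intermediate", "strong"],
      "til_percent": [0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100]
    },
    "LP": {
      "ar_percent": [0, 1, 5, 10, 20, 30],
      "ar_intensity": ["negative", "weak", "intermediate"],
      "til_percent": [60, 70, 80, 90, 100]
    },
    "LI": {
      "ar_percent": [0, 1, 5, 10, 20, 30],
      "ar_intensity": ["negative", "weak", "intermediate"],
      "til_percent": [20, 30, 40, 50]
    },
    "LD": {
      "ar_percent": [0, 1, 5, 10, 20, 30],
      "ar_intensity": ["negative", "weak", "intermediate"],
      "til_percent": [0, 10]
    }
  },
  "hr_map": {
    "os":  {"LAR": 2.0, "LP": 1.0, "LI": 3.0, "LD": 11.8},
    "rfs": {"LAR": 1.5, "LP": 1.0, "LI": 2.0, "LD": 3.68},
    "dfs": {"LAR": 1.5, "LP": 1.0, "LI": 2.0, "LD": 3.81}
  },
  "baseline_hazard": 0.005,
  "censor_rate": 0.01,
  "alteration_frequencies": [
    {"gene": "PIK3CA",   "event_type": "mutation",      "LAR": 0.45, "LP": 0.10, "LI": 0.10, "LD": 0.10},
    {"gene": "CD274",    "event_type": "deletion",      "LAR": 0.30, "LP": 0.05, "LI": 0.05, "LD": 0.05},
    {"gene": "PDCD1LG2", "event_type": "deletion",      "LAR": 0.30, "LP": 0.05, "LI": 0.05, "LD": 0.05},
    {"gene": "B2M",      "event_type": "deletion",      "LAR": 0.05, "LP": 0.25, "LI": 0.05, "LD": 0.05},
    {"gene": "NOTCH2",   "event_type": "amplification", "LAR": 0.05, "LP": 0.05, "LI": 0.05, "LD": 0.30},
    {"gene": "MYC",      "event_type": "amplification", "LAR": 0.10, "LP": 0.10, "LI": 0.10, "LD": 0.40}
  ],
  "hrd_params": {
    "mean": {"LAR": 15, "LP": 30, "LI": 35, "LD": 50},
    "sd": 12
  }
}
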