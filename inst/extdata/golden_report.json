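{
  "scores": [
    {
      "narrative_id": "NS001",
      "subject_id": "S001",
      "openness_score": 39,
      "n_matches": 13
    },
    {
      "narrative_id": "NS002",
      "subject_id": "S002",
      "openness_score": 30,
      "n_matches": 10
    },
    {
      "narrative_id": "NS003",
      "subject_id": "S003",
      "openness_score": 33,
      "n_matches": 11
    },
    {
      "narrative_id": "NS004",
      "subject_id": "S004",
      "openness_score": 3,
      "n_matches": 1
    },
    {
      "narrative_id": "NS005",
      "subject_id": "S005",
      "openness_score": 45,
      "n_matches": 15
    },
    {
      "narrative_id": "NS006",
      "subject_id": "S006",
      "openness_score": 3,
      "n_matches": 1
    },
    {
      "narrative_id": "NS007",
      "subject_id": "S007",
      "openness_score": 15,
      "n_matches": 5
    },
    {
      "narrative_id": "NS008",
      "subject_id": "S008",
      "openness_score": 24,
      "n_matches": 8
    },
    {
      "narrative_id": "NS009",
      "subject_id": "S009",
      "openness_score": 30,
      "n_matches": 10
    },
    {
      "narrative_id": "NS010",
      "subject_id": "S010",
      "openness_score": 42,
      "n_matches": 14
    },
    {
      "narrative_id": "NS011",
      "subject_id": "S011",
      "openness_score": 30,
      "n_matches": 10
    },
    {
      "narrative_id": "NS012",
      "subject_id": "S012",
      "openness_score": 15,
      "n_matches": 5
    }
  ],
  "score_summary": {
    "mean": 25.75,
    "sd": 14.0978721798717,
    "min": 3,
    "max": 45,
    "n": 12
  },
  "collinearity_dropped": [
    {
      "dropped": "informational_support",
      "kept_partner": "single",
      "r": -0.797724035217465
    }
  ],
  "selected": [],
  "coefficients": [
    {
      "term": "(Intercept)",
      "estimate": 24.75,
      "se": 4.45513347563395,
      "t": 5.55538911131683,
      "p": 0.000855051234035955
    }
  ],
  "r_squared": 0,
  "adj_r_squared": 0,
  "threshold": 30,
  "split": {
    "seed": 7,
    "train_fraction": 0.7,
    "train_ids": ["S002", "S003", "S006", "S007", "S009", "S010", "S011", "S012"],
    "test_ids": ["S001", "S004", "S005", "S008"]
  },
  "train": {
    "n": 8,
    "rmse": 11.7871752341263,
    "auc": 0.5,
    "sensitivity": 1,
    "specificity": 0,
    "accuracy": 0.25,
    "cut": 23.75
  },
  "test": {
    "n": 4,
    "rmse": 16.4829457318769,
    "auc": 0.5,
    "sensitivity": 1,
    "specificity": 0,
    "accuracy": 0.5,
    "cut": 23.75
  }
}
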