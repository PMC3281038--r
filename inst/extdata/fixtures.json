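[
  {
    "name": "flowers-clean",
    "type": "decision",
    "tag": "reference",
    "note": "two flowers compared on odor/color/shape; error-free perception",
    "cues_a": [1, 0, 1],
    "cues_b": [1, 1, 0],
    "cue_order": [1, 2, 3],
    "expected_choice": "B",
    "expected_stopping_cue": 2
  },
  {
    "name": "flowers-misperceived",
    "type": "decision",
    "tag": "reference",
    "note": "same pair, but the agent misreads B's color cue (1 -> 0)",
    "cues_a": [1, 0, 1],
    "cues_b": [1, 0, 0],
    "cue_order": [1, 2, 3],
    "expected_choice": "A",
    "expected_stopping_cue": 3
  },
  {
    "name": "three-option-validity",
    "type": "validity",
    "tag": "derived",
    "note": "hand enumeration over the three option pairs: one right, one wrong, one non-discriminating",
    "criterion": [3, 2, 1],
    "cues_bin": [1, 0, 1],
    "expected_validity": 0.5,
    "expected_n_right": 1,
    "expected_n_wrong": 1
  },
  {
    "name": "table1-LD",
    "type": "environment",
    "tag": "reference",
    "environment": "LD",
    "expected_sum_sq": 0.2408,
    "expected_variance_explained": 0.865,
    "expected_validities": [0.86, 0.71, 0.6, 0.57, 0.54],
    "validity_tolerance": 0.01
  },
  {
    "name": "table1-MD",
    "type": "environment",
    "tag": "reference",
    "environment": "MD",
    "expected_sum_sq": 0.1878,
    "expected_variance_explained": 0.864,
    "expected_validities": [0.78, 0.71, 0.67, 0.64, 0.61],
    "validity_tolerance": 0.01
  },
  {
    "name": "table1-SD",
    "type": "environment",
    "tag": "reference",
    "environment": "SD",
    "expected_sum_sq": 0.168,
    "expected_variance_explained": 0.866,
    "expected_validities": [0.71, 0.7, 0.69, 0.68, 0.67],
    "validity_tolerance": 0.01
  },
  {
    "name": "table1-ND",
    "type": "environment",
    "tag": "reference",
    "environment": "ND",
    "expected_sum_sq": 0.167,
    "expected_variance_explained": 0.865,
    "expected_validities": [0.69, 0.69, 0.69, 0.69, 0.69],
    "validity_tolerance": 0.01
  }
]
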