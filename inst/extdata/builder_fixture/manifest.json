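{
  "n_responses": 5,
  "retained": ["P1", "P2", "P4", "P5"],
  "excluded": [
    {
      "participant_id": "P3",
      "reason": "only 3 valid days"
    }
  ],
  "labels": {
    "P1": 1,
    "P2": 0,
    "P4": 1,
    "P5": 0
  },
  "valid_day_flags": {
    "P1": [true, true, true, true, true, true, true, true],
    "P2": [true, true, true, true, false, false, false, false],
    "P3": [true, true, true, false, false, false, false, false],
    "P4": [true, true, false, true, false, true, false, true],
    "P5": [true, true, true, false, true, true, true, false]
  },
  "valid_day_counts": {
    "P1": 8,
    "P2": 4,
    "P3": 3,
    "P4": 5,
    "P5": 6
  },
  "imputed": {
    "participant_id": "P2",
    "feature": "sdnn",
    "days_filled": [5, 6, 7, 8],
    "value": 50,
    "collapsed": 50
  },
  "dataset_shapes": {
    "sleep": [4, 6],
    "hrv": [3, 7],
    "pa": [4, 28],
    "sleep+hrv": [3, 13],
    "sleep+pa": [4, 34],
    "hrv+pa": [3, 35],
    "all": [3, 41]
  }
}
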