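{
  "tp": 883,
  "tn": 124,
  "fp": 165,
  "fn": 5,
  "sensitivity": 0.994369,
  "specificity": 0.429066,
  "accuracy": 0.855565,
  "precision": 0.842557
}
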