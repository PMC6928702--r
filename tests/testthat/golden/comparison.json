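{
  "test_used": "wilcoxon_ranksum",
  "variance_test_p": "NA",
  "p_value": 0.741776,
  "significant": false,
  "alpha": 0.05
}
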