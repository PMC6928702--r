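"bout_id","start_s","end_s","n_steps","n_cycles","first_side"
1,"5.025000","63.540000",100,50,"left"
2,"75.070000","129.485000",94,47,"left"
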