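"method","n","mean","sd","median","minimum","maximum","q1","q3","skewness","kurtosis"
"A",83,"1.144107","0.112361","1.154138","0.863281","1.328550","1.057234","1.231309","-0.452251","2.414891"
"B",3,"1.125757","0.120787","1.186773","0.986634","1.203865","1.086704","1.195319","-0.691211","1.500000"
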