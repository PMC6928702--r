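"method","speed","fraction"
"A","0.863281","0.012048"
"A","0.870566","0.024096"
"A","0.944174","0.036145"
"A","0.947055","0.048193"
"A","0.953674","0.060241"
"A","0.958570","0.072289"
"A","0.973584","0.084337"
"A","0.979726","0.096386"
"A","0.981750","0.108434"
"A","0.986845","0.120482"
"A","0.990781","0.132530"
"A","0.999116","0.144578"
"A","1.011113","0.156627"
"A","1.016538","0.168675"
"A","1.020177","0.180723"
"A","1.031936","0.192771"
"A","1.040004","0.204819"
"A","1.040623","0.216867"
"A","1.047687","0.228916"
"A","1.049327","0.240964"
"A","1.052866","0.253012"
"A","1.061602","0.265060"
"A","1.070370","0.277108"
"A","1.082313","0.289157"
"A","1.082618","0.301205"
"A","1.097200","0.313253"
"A","1.097713","0.325301"
"A","1.100219","0.337349"
"A","1.103950","0.349398"
"A","1.105112","0.361446"
"A","1.118687","0.373494"
"A","1.123097","0.385542"
"A","1.129871","0.397590"
"A","1.131649","0.409639"
"A","1.135584","0.421687"
"A","1.137343","0.433735"
"A","1.140057","0.445783"
"A","1.146870","0.457831"
"A","1.148075","0.469880"
"A","1.151822","0.481928"
"A","1.152773","0.493976"
"A","1.154138","0.506024"
"A","1.161137","0.518072"
"A","1.176699","0.530120"
"A","1.178336","0.542169"
"A","1.180033","0.554217"
"A","1.184540","0.566265"
"A","1.184719","0.578313"
"A","1.189401","0.590361"
"A","1.190412","0.602410"
"A","1.194854","0.614458"
"A","1.196275","0.626506"
"A","1.199990","0.638554"
"A","1.205056","0.650602"
"A","1.207847","0.662651"
"A","1.210601","0.674699"
"A","1.210618","0.686747"
"A","1.211423","0.698795"
"A","1.215913","0.710843"
"A","1.221725","0.722892"
"A","1.224960","0.734940"
"A","1.226792","0.746988"
"A","1.235826","0.759036"
"A","1.239536","0.771084"
"A","1.241713","0.783133"
"A","1.249748","0.795181"
"A","1.251044","0.807229"
"A","1.252053","0.819277"
"A","1.252902","0.831325"
"A","1.254394","0.843373"
"A","1.256232","0.855422"
"A","1.257347","0.867470"
"A","1.260862","0.879518"
"A","1.263234","0.891566"
"A","1.273780","0.903614"
"A","1.281371","0.915663"
"A","1.300550","0.927711"
"A","1.306174","0.939759"
"A","1.307221","0.951807"
"A","1.307635","0.963855"
"A","1.316823","0.975904"
"A","1.322086","0.987952"
"A","1.328550","1.000000"
"B","0.986634","0.333333"
"B","1.186773","0.666667"
"B","1.203865","1.000000"
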