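composition,Js,ratio
70:0:30:0,-0.060,1
60:0:30:10,-0.147,3.76
40:30:30:0,-0.125,1.17
30:30:30:10,-0.213,12.82
20:50:30:0,-0.169,2.02
10:50:30:10,-0.256,23.67
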