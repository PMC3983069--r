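motif,R1,R2,ratio
ALPS1,34,90,46.75
ALPS1,42,90,11.51
ALPS1,90,90,1
ALPS2,34,90,5.33
ALPS2,42,90,2.25
ALPS2,90,90,1
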