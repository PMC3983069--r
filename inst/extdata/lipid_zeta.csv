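name,zeta_per_nm
DOPC,-0.115
DOPE,-0.333
DOPS,0.068
DAG,-0.985
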