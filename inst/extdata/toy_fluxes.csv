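reaction,flux
v1,2
v2,0.5
v3,1
v4_f,1
v4_b,0.5
v5_f,1
v5_b,1
v6,1
v7,1
v8,1
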