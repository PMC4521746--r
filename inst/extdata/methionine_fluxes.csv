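reaction,flux
v_upt,3
v_mat,5
v_mt,4
v_sahh,4
v_ms,2
v_samdc_spds,1
v_salvage,1
v_prot,1
v_cbs,2
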