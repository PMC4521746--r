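# Synthetic reconstruction of a small mammalian methionine-metabolism model
# (transmethylation cycle, polyamine biosynthesis, methionine salvage).
# Carbon bookkeeping: Met 1-4 backbone + 5 S-methyl; SAM 1-4 backbone,
# 5 methyl, 6-10 adenine, 11-15 ribose; SAH = SAM minus methyl; MTA 1-5
# adenine, 6-10 ribose, 11 methyl.  Media: methionine (Met_media), ATP
# (adenine 1-5 + ribose 6-10), 5-methyl-THF methyl carbon (CH3THF).
#media ATP CH3THF Met_media
v_upt: Met_media (abcde) -> Met (abcde)
v_mat: Met (abcde) + ATP (fghijklmno) -> SAM (abcdefghijklmno)
v_mt: SAM (abcdefghijklmno) -> SAH (abcdfghijklmno)
v_sahh: SAH (abcdefghijklmn) -> HCys (abcd)
v_ms: HCys (abcd) + CH3THF (e) -> Met (abcde)
v_samdc_spds: SAM (abcdefghijklmno) -> MTA (fghijklmnoe)
v_salvage: MTA (abcdefghijk) -> Met (fghik)
v_prot: Met (abcde) ->
v_cbs: HCys (abcd) ->
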