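#media A
v1: A (abcd) -> B (abcd)
v2: A (abcd) -> C (ab) + D (dc)
v3: B (abcd) -> C (cd)
v4: C (ab) <-> D (ab)
v5: B (abcd) <-> E (abcd)
v6: B (abcd) + C (ef) -> E (cdef)
v7: D (ab) ->
v8: E (abcd) ->
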