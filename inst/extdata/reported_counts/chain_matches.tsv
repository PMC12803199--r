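class	n_matches
odd_chain_total	43563
even_chain_total	45531
C3:0	17893
saturated_total	89094
unsaturated_total	3933
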