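adduct	n_spectra
[M+H]+	416
[M+Na]+	147
[M+K]+	25
[M+NH4]+	53
[M-H2O+H]+	122
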