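repository	n_files
Metabolights	1025
Metabolomics Workbench	59
GNPS/MassIVE	53660
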