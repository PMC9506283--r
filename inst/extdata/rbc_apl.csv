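species,nchol,chol,kchol
DPPC,48.5,44.7,45.3
DPPE,46.9,43.9,44.8
DPPS,45.0,43.9,46.6
PSM,43.2,41.9,45.9
sterol,NA,21.8,23.8
average_all,NA,39.4,41.2
average_lipid_only,46.1,43.8,45.5
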