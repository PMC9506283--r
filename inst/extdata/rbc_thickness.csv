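species,measure,nchol,chol,kchol
DPPC,tail,16.1,18.1,17.9
DPPE,tail,16.3,18.2,17.7
DPPS,tail,16.8,18.3,17.8
PSM,tail,17.9,19.4,18.4
All,tail,16.6,18.3,17.8
DPPC,head,7.6,7.4,7.4
DPPE,head,6.2,6.1,6.2
DPPS,head,8.1,7.8,7.9
PSM,head,6.6,6.6,6.2
All,head,7.0,6.8,6.8
DPPC,total,23.6,25.5,25.3
DPPE,total,22.5,24.3,23.9
DPPS,total,24.9,26.1,25.7
PSM,total,24.5,25.9,24.5
All,total,23.6,25.1,24.7
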