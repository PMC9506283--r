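system,pressure,epsilon
chol,30,147
nchol,30,207
kchol,30,250
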