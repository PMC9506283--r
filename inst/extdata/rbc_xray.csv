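system,qxy_peak,lc,d_tail,d_head,first_minimum
chol,1.50360,178,17.3,9.0,0.2151
nchol,1.50360,169,17.9,8.8,0.2094
kchol,1.5031,128,15.8,11.2,0.2235
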