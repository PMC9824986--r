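link,AIC,BIC
probit,13727.7,14041.7
logit,13720.2,14025.3
cloglog,13717.2,14022.3
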