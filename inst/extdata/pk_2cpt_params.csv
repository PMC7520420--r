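agent,species,Vc,CL,Vp,Q
PF-06804103,mouse,61.0,22.8,56.2,35.0
PF-06804103,monkey,38.1,7.2,20.2,19.2
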