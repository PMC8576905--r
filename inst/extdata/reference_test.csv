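experiment,accuracy,fnr
1,0.9907,0.0092
2,0.9824,0.0175
3,0.9814,0.0185
mean,0.9848,0.0150
sd,0.0051,NA
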