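combination,train_snr,val_snr,snr_sum
1,23.76,18.48,42.24
2,26.81,24.01,50.83
3,24.20,18.35,42.56
4,31.87,24.31,56.19
5,26.99,22.30,49.30
6,24.53,22.39,46.93
7,27.07,23.96,51.04
8,25.86,22.74,48.62
9,24.54,22.06,46.61
10,28.79,23.68,52.48
11,26.73,24.39,51.13
12,30.80,23.42,54.22
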