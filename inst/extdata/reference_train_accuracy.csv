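combination,acc_1,acc_2,acc_3,mean,sd,snr
1,0.9340,0.9338,0.9378,0.9352,0.002254,23.76
2,0.9586,0.9463,0.9602,0.9550,0.007606,26.81
3,0.9388,0.9365,0.9398,0.9383,0.001692,24.20
4,0.9678,0.9780,0.9805,0.9754,0.006728,31.87
5,0.9567,0.9551,0.9541,0.9553,0.001312,26.99
6,0.9404,0.9398,0.9418,0.9406,0.001026,24.53
7,0.9557,0.9557,0.9558,0.9557,0.000058,27.07
8,0.9487,0.9544,0.9449,0.9493,0.004782,25.86
9,0.9408,0.9406,0.9408,0.9407,0.000116,24.54
10,0.9528,0.9722,0.9710,0.9653,0.010871,28.79
11,0.9536,0.9527,0.9556,0.9539,0.001484,26.73
12,0.9725,0.9761,0.9662,0.9716,0.005011,30.80
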