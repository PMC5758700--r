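sample_id,variable_set,actual_class,flag,y_pre,y_dev
BFL-01,full886,1,ok,0.836,0.116
BFL-01,cars,1,ok,1.001,0.001
BFL-01,mcuve,1,ok,0.654,0.245
BFL-01,spa,1,ok,1.023,0.016
BFL-01,lpg,1,ok,0.805,0.138
BFL-05,full886,1,ok,1.629,0.445
BFL-05,cars,1,ok,0.774,0.160
BFL-05,mcuve,1,ok,0.644,0.252
BFL-05,spa,1,ok,1.230,0.163
BFL-05,lpg,1,ok,0.548,0.320
BFL-20,full886,1,ok,1.536,0.379
BFL-20,cars,1,ok,0.834,0.117
BFL-20,mcuve,1,ok,0.541,0.324
BFL-20,spa,1,ok,0.805,0.138
BFL-20,lpg,1,ok,0.749,0.178
BFL-34,full886,1,ok,1.618,0.437
BFL-34,cars,1,ok,0.719,0.199
BFL-34,mcuve,1,ok,0.621,0.268
BFL-34,spa,1,ok,1.205,0.145
BFL-34,lpg,1,ok,0.762,0.168
BFL-40,full886,1,ok,0.835,0.117
BFL-40,cars,1,ok,1.168,0.119
BFL-40,mcuve,1,ok,0.711,0.204
BFL-40,spa,1,ok,1.577,0.408
BFL-40,lpg,1,ok,0.822,0.126
BFL-48,full886,1,suspicious,1.782,0.553
BFL-48,cars,1,ok,1.119,0.084
BFL-48,mcuve,1,ok,0.685,0.223
BFL-48,spa,1,ok,1.400,0.283
BFL-48,lpg,1,ok,0.725,0.194
BFL-33,full886,2,ok,2.004,0.003
BFL-33,cars,2,ok,2.084,0.059
BFL-33,mcuve,2,ok,1.756,0.173
BFL-33,spa,2,ok,1.849,0.107
BFL-33,lpg,2,ok,1.758,0.171
BFL-42,full886,2,suspicious,2.635,0.450
BFL-42,cars,2,ok,1.554,0.315
BFL-42,mcuve,2,ok,1.539,0.326
BFL-42,spa,2,ok,1.870,0.092
BFL-42,lpg,2,ok,1.682,0.225
BFL-49,full886,2,ok,1.928,0.051
BFL-49,cars,2,ok,1.593,0.288
BFL-49,mcuve,2,ok,2.192,0.136
BFL-49,spa,2,ok,1.963,0.026
BFL-49,lpg,2,ok,1.920,0.057
BFL-54,full886,2,ok,1.845,0.110
BFL-54,cars,2,ok,1.967,0.023
BFL-54,mcuve,2,ok,1.963,0.026
BFL-54,spa,2,ok,1.720,0.198
BFL-54,lpg,2,ok,1.821,0.126
BFL-55,full886,2,ok,1.751,0.176
BFL-55,cars,2,ok,1.942,0.041
BFL-55,mcuve,2,ok,1.882,0.083
BFL-55,spa,2,ok,2.034,0.024
BFL-55,lpg,2,ok,1.716,0.201
BFL-12,full886,3,ok,2.802,0.140
BFL-12,cars,3,ok,3.019,0.013
BFL-12,mcuve,3,ok,2.562,0.310
BFL-12,spa,3,ok,2.880,0.085
BFL-12,lpg,3,ok,2.575,0.300
BFL-15,full886,4,ok,3.844,0.110
BFL-15,cars,4,ok,4.593,0.419
BFL-15,mcuve,4,ok,3.744,0.181
BFL-15,spa,4,ok,3.876,0.088
BFL-15,lpg,4,ok,3.582,0.296
BFL-37,full886,4,ok,3.948,0.037
BFL-37,cars,4,ok,3.712,0.204
BFL-37,mcuve,4,ok,3.720,0.198
BFL-37,spa,4,ok,3.900,0.071
BFL-37,lpg,4,ok,3.807,0.137
BFL-47,full886,4,ok,3.893,0.076
BFL-47,cars,4,ok,3.873,0.090
BFL-47,mcuve,4,ok,3.861,0.098
BFL-47,spa,4,ok,3.657,0.243
BFL-47,lpg,4,ok,3.817,0.129
BFL-04,full886,5,suspicious,5.653,0.462
BFL-04,cars,5,ok,4.901,0.070
BFL-04,mcuve,5,ok,4.782,0.154
BFL-04,spa,5,ok,4.565,0.308
BFL-04,lpg,5,ok,4.576,0.300
BFL-13,full886,5,ok,4.813,0.132
BFL-13,cars,5,ok,5.126,0.089
BFL-13,mcuve,5,ok,5.117,0.083
BFL-13,spa,5,ok,4.685,0.223
BFL-13,lpg,5,ok,4.790,0.149
BFL-16,full886,5,ok,4.904,0.068
BFL-16,cars,5,ok,5.047,0.033
BFL-16,mcuve,5,ok,4.751,0.176
BFL-16,spa,5,ok,4.818,0.129
BFL-16,lpg,5,ok,5.013,0.009
BFL-25,full886,5,ok,4.965,0.025
BFL-25,cars,5,ok,4.829,0.121
BFL-25,mcuve,5,ok,4.995,0.004
BFL-25,spa,5,ok,4.762,0.168
BFL-25,lpg,5,ok,4.829,0.121
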