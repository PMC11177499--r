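site,model,trait,sigma2_A,se_A,sigma2_e,se_e,h2,se_h2
Horeda,A,DBH12,92.578,12.996,203.693,12.117,0.312,0.042
Horeda,A,DBH21,308.773,42.882,599.653,39.694,0.339,0.045
Horeda,A,HI7,1537.417,194.117,2488.117,175.284,0.381,0.045
Horeda,A,RWT,0.456,0.049,0.107,0.041,0.809,0.076
Horeda,A,PILOD,3.759,0.462,2.174,0.401,0.633,0.070
Horeda,A,DENS,1414.590,144.142,151.082,119.165,0.903,0.077
Horeda,A,MOE,2.196,0.325,2.382,0.295,0.479,0.066
Horeda,A,MFA,3.703,1.034,14.203,1.045,0.206,0.057
Horeda,A,TRadW,2.669,0.296,0.801,0.250,0.769,0.074
Horeda,A,TTangW,1.015,0.159,1.290,0.146,0.440,0.065
Horeda,A,TWTH,0.024,0.002,0.011,0.002,0.681,0.072
Horeda,A,TC,406.816,68.393,613.229,63.996,0.398,0.064
Horeda,A,NUMRES,33.566,7.761,87.851,7.613,0.276,0.062
Horeda,A,AVCAREA,12238.63,2250.014,20698.93,2127.098,0.371,0.065
Horeda,A,CANDENS,52.721,11.963,149.329,11.733,0.260,0.057
Horeda,A,CELL,0.236,0.081,0.715,0.081,0.249,0.084
Horeda,A,HEM,0.031,0.013,0.134,0.014,0.189,0.082
Horeda,A,LIG,0.103,0.026,0.186,0.025,0.357,0.087
Horeda,B,DBH12,55.205,10.737,232.319,10.874,0.192,0.036
Horeda,B,DBH21,145.287,33.176,723.673,34.254,0.167,0.037
Horeda,B,HI7,1283.008,180.207,2679.159,167.396,0.323,0.043
Horeda,B,RWT,0.288,0.039,0.234,0.034,0.551,0.069
Horeda,B,PILOD,2.776,0.406,2.913,0.366,0.487,0.066
Horeda,B,DENS,1069.350,123.840,410.860,105.611,0.722,0.074
Horeda,B,MOE,1.631,0.292,2.808,0.275,0.367,0.063
Horeda,B,MFA,3.105,1.003,14.651,1.028,0.174,0.055
Horeda,B,TRadW,2.330,0.277,1.055,0.238,0.688,0.073
Horeda,B,TTangW,0.904,0.153,0.897,0.148,0.397,0.064
Horeda,B,TWTH,0.019,0.002,0.015,0.002,0.562,0.069
Horeda,B,TC,383.576,67.456,631.353,63.482,0.377,0.063
Horeda,B,NUMRES,30.420,7.628,90.322,7.548,0.251,0.062
Horeda,B,AVCAREA,11354.158,2208.23,21369.810,2442.938,0.346,0.065
Horeda,B,CANDENS,39.792,10.931,159.102,11.055,0.200,0.054
Horeda,B,CELL,0.228,0.081,0.721,0.081,0.240,0.084
Horeda,B,HEM,0.030,0.013,0.135,0.014,0.183,0.082
Horeda,B,LIG,0.097,0.025,0.191,0.024,0.337,0.087
Erikstorp,A,DBH12,144.117,18.831,235.604,17.106,0.379,0.046
Erikstorp,A,DBH21,197.469,37.468,555.135,36.588,0.262,0.048
Erikstorp,A,HI7,1326.204,185.363,2730.078,172.451,0.326,0.043
Erikstorp,A,RWT,0.319,0.048,0.299,0.043,0.515,0.073
Erikstorp,A,PILOD,2.931,0.539,4.476,0.507,0.395,0.069
Erikstorp,A,DENS,877.921,113.879,449.547,99.470,0.661,0.077
Erikstorp,A,MOE,1.931,0.350,2.819,0.328,0.406,0.070
Erikstorp,A,MFA,4.426,1.393,17.583,1.412,0.201,0.062
Erikstorp,A,TRadW,1.712,0.227,0.935,0.199,0.646,0.078
Erikstorp,A,TTangW,0.951,0.151,1.005,0.137,0.486,0.073
Erikstorp,A,TWTH,0.016,0.002,0.013,0.002,0.540,0.073
Erikstorp,A,TC,316.083,56.237,454.171,52.736,0.410,0.069
Erikstorp,A,NUMRES,42.782,11.883,101.805,11.647,0.295,0.080
Erikstorp,A,AVCAREA,7732.33,2437.293,22818.36,2423.491,0.253,0.078
Erikstorp,A,CANDENS,48.423,11.586,103.229,11.154,0.319,0.074
Erikstorp,A,CELL,0.267,0.090,0.721,0.089,0.270,0.089
Erikstorp,A,HEM,0.036,0.011,0.093,0.011,0.282,0.090
Erikstorp,A,LIG,0.074,0.030,0.267,0.030,0.216,0.087
Erikstorp,B,DBH12,72.496,14.085,289.447,14.229,0.200,0.038
Erikstorp,B,DBH21,71.435,26.931,648.502,30.298,0.099,0.037
Erikstorp,B,HI7,883.436,153.294,3057.163,152.214,0.224,0.038
Erikstorp,B,RWT,0.154,0.038,0.422,0.037,0.267,0.065
Erikstorp,B,PILOD,2.592,0.524,4.739,0.499,0.353,0.068
Erikstorp,B,DENS,694.502,103.063,587.734,92.554,0.541,0.074
Erikstorp,B,MOE,1.481,0.323,3.155,0.311,0.319,0.067
Erikstorp,B,MFA,3.898,1.363,17.965,1.394,0.178,0.061
Erikstorp,B,TRadW,1.590,0.220,1.025,0.194,0.608,0.077
Erikstorp,B,TTangW,0.897,0.148,1.045,0.136,0.461,0.072
Erikstorp,B,TWTH,0.013,0.002,0.015,0.002,0.459,0.071
Erikstorp,B,TC,299.292,55.570,466.891,52.340,0.390,0.069
Erikstorp,B,NUMRES,41.332,11.769,102.707,11.565,0.286,0.079
Erikstorp,B,AVCAREA,7999.531,2471.36,22602.401,2442.938,0.261,0.079
Erikstorp,B,CANDENS,44.767,11.611,106.004,11.265,0.296,0.074
Erikstorp,B,CELL,0.279,0.091,0.712,0.089,0.281,0.090
Erikstorp,B,HEM,0.038,0.012,0.092,0.011,0.293,0.092
Erikstorp,B,LIG,0.077,0.030,0.264,0.030,0.225,0.087
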