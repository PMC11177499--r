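site,trait,pa_A,pa_se_A,pa_B,pa_se_B,acc_A,acc_B
Horeda,DBH21,0.171,0.007,0.211,0.009,0.292,0.523
Horeda,DBH12,0.146,0.008,0.173,0.008,0.271,0.418
Horeda,HI7,0.156,0.008,0.165,0.008,0.259,0.298
Horeda,RWT,0.282,0.014,0.312,0.011,0.307,0.413
Horeda,DENS,0.310,0.011,0.329,0.009,0.325,0.391
Horeda,PILOD,0.216,0.014,0.240,0.017,0.279,0.360
Horeda,MOE,0.192,0.019,0.221,0.018,0.293,0.393
Horeda,MFA,0.097,0.010,0.114,0.017,0.220,0.285
Horeda,TTangW,0.184,0.013,0.199,0.014,0.276,0.318
Horeda,TRadW,0.286,0.008,0.299,0.010,0.326,0.363
Horeda,TWTH,0.247,0.008,0.266,0.006,0.294,0.352
Horeda,TC,0.168,0.009,0.176,0.004,0.254,0.274
Horeda,NUMRES,0.115,0.019,0.114,0.014,0.213,0.221
Horeda,AVCAREA,0.141,0.013,0.150,0.017,0.224,0.246
Horeda,CANDENS,0.088,0.021,0.122,0.027,0.178,0.282
Horeda,LIG,0.118,0.008,0.132,0.009,0.190,0.218
Horeda,CELL,0.081,0.014,0.095,0.017,0.156,0.184
Horeda,HEM,0.077,0.015,0.078,0.010,0.172,0.175
Erikstorp,DBH21,0.114,0.014,0.203,0.015,0.220,0.682
Erikstorp,DBH12,0.194,0.009,0.244,0.011,0.306,0.529
Erikstorp,HI7,0.173,0.009,0.201,0.013,0.291,0.399
Erikstorp,RWT,0.209,0.015,0.277,0.010,0.282,0.504
Erikstorp,DENS,0.247,0.007,0.268,0.008,0.294,0.354
Erikstorp,PILOD,0.143,0.010,0.159,0.009,0.221,0.265
Erikstorp,MOE,0.151,0.009,0.194,0.013,0.229,0.332
Erikstorp,MFA,0.075,0.009,0.111,0.015,0.162,0.257
Erikstorp,TTangW,0.211,0.018,0.217,0.018,0.301,0.318
Erikstorp,TRadW,0.248,0.027,0.251,0.023,0.318,0.332
Erikstorp,TWTH,0.209,0.010,0.225,0.009,0.267,0.313
Erikstorp,TC,0.173,0.023,0.170,0.020,0.253,0.257
Erikstorp,NUMRES,0.110,0.090,0.122,0.020,0.190,0.211
Erikstorp,AVCAREA,0.083,0.015,0.082,0.015,0.167,0.167
Erikstorp,CANDENS,0.117,0.010,0.125,0.006,0.210,0.233
Erikstorp,LIG,0.061,0.017,0.055,0.019,0.126,0.112
Erikstorp,CELL,0.063,0.016,0.050,0.016,0.118,0.092
Erikstorp,HEM,0.083,0.015,0.051,0.007,0.159,0.179
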