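decile,n_occ,pixels_suitable,pct_area,test_auc,test_auc_sd,train_auc,omission_rate
1,39,16840,10.7,0.797,0.090,0.950,0.077
2,46,47386,30.2,0.875,0.056,0.933,0.043
3,41,52064,33.2,0.845,0.071,0.913,0.098
4,39,41900,27.2,0.884,0.049,0.920,0.077
5,38,49687,31.7,0.812,0.067,0.896,0.079
6,39,32359,20.6,0.848,0.050,0.911,0.077
7,39,40574,25.9,0.831,0.050,0.900,0.077
8,44,29752,19.0,0.886,0.042,0.940,0.091
9,41,32326,20.6,0.856,0.052,0.902,0.098
10,34,17959,11.5,0.879,0.049,0.943,0.088
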