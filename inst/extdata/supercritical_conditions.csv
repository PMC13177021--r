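condition,temperature_K,pressure_bar,density_sim_kgm3,density_exp_kgm3,error_pct
1,679.451,551.780,584.852,581.043,0.656
2,679.441,606.894,601.227,599.995,0.205
3,679.448,662.010,615.569,616.043,0.077
4,679.454,717.096,628.451,630.040,0.252
5,679.449,772.485,640.036,642.582,0.396
6,711.805,551.690,505.245,485.125,4.147
7,711.814,606.844,529.353,516.209,2.546
8,711.815,661.918,549.482,540.903,1.586
9,711.809,716.868,566.706,561.344,0.955
10,711.809,772.345,581.943,578.963,0.515
11,744.167,551.574,419.497,377.487,11.129
12,744.171,606.735,450.922,421.276,7.037
13,744.159,661.966,478.421,456.273,4.854
14,744.162,717.228,501.073,484.784,3.360
15,744.152,772.460,520.543,508.587,2.351
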