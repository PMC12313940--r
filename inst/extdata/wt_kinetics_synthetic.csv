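substrate_mM,rate_M_per_s
0.05,5.7858e-08
0.05,7.14669e-08
0.05,5.94504e-08
0.1,1.07347e-07
0.1,1.16031e-07
0.1,1.17337e-07
0.2,2.43806e-07
0.2,1.96813e-07
0.2,1.93842e-07
0.5,4.42105e-07
0.5,4.46586e-07
0.5,3.81949e-07
1,5.90134e-07
1,6.02681e-07
1,5.9587e-07
2,7.3639e-07
2,7.38482e-07
2,7.28114e-07
4,8.26942e-07
4,8.32686e-07
4,8.80613e-07
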