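group,females,males,weighted_census_mf,weighted_aps_all_mf,weighted_aps_utly_mf
1,28,33,1.02,1.28,1.31
2,18,42,1.16,1.33,1.29
3,18,39,1.51,2.07,1.81
4,18,58,2.60,2.45,3.98
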