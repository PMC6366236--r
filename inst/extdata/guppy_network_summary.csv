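population,quantity,n,value,null_median,p
HP,network_size,61,61,NA,NA
LP,network_size,102,102,NA,NA
HP,dyads,61,1830,NA,NA
LP,dyads,102,5151,NA,NA
HP,assort_body_length_weighted,61,0.17,0.00,0.00
LP,assort_body_length_weighted,102,0.38,0.03,0.00
HP,assort_sex_weighted,61,0.02,-0.03,0.11
LP,assort_sex_weighted,102,0.39,0.05,0.00
HP,spearman_bodylength_coop,61,-0.19,NA,0.15
LP,spearman_bodylength_coop,102,-0.21,NA,0.037
HP,mannwhitney_sex_coop_W,61,413,NA,0.92
LP,mannwhitney_sex_coop_W,102,1729,NA,0.0034
HP,dyadic_summed_coop_r,1830,0.00,0.00,0.83
LP,dyadic_summed_coop_r,5151,0.02,0.00,0.16
HP,dyadic_relatedness_r,1830,-0.02,-0.01,0.50
LP,dyadic_relatedness_r,5151,0.00,0.00,0.94
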