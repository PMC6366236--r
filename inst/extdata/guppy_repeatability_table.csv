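subset,river,population,n,F,p_value,repeatability,significant
all,Aripo,HP,105,2.48,<0.0001,0.43,yes
all,Aripo,LP,144,1.73,0.0006,0.27,yes
all,Turure,HP,97,2.47,<0.0001,0.42,yes
all,Turure,LP,139,1.20,0.14,0.09,no
all,Guanapo,HP,136,1.69,0.0012,0.26,yes
all,Guanapo,LP,144,2.15,<0.0001,0.36,yes
all,Lopinot,HP,136,1.44,0.017,0.18,yes
all,Lopinot,LP,146,1.57,0.0036,0.22,yes
females,Aripo,HP,53,2.18,0.0035,0.37,yes
females,Aripo,LP,74,1.90,0.0042,0.31,yes
females,Turure,HP,48,4.17,<0.0001,0.61,yes
females,Turure,LP,72,1.34,0.11,0.15,no
females,Guanapo,HP,73,1.92,0.0031,0.32,yes
females,Guanapo,LP,73,2.24,0.0004,0.38,yes
females,Lopinot,HP,74,1.48,0.048,0.19,no
females,Lopinot,LP,74,1.57,0.028,0.22,yes
males,Aripo,HP,52,2.86,0.0002,0.48,yes
males,Aripo,LP,70,1.38,0.094,0.16,no
males,Turure,HP,49,1.64,0.044,0.24,no
males,Turure,LP,67,0.98,0.53,-0.01,no
males,Guanapo,HP,63,1.45,0.074,0.18,no
males,Guanapo,LP,71,1.87,0.0051,0.30,yes
males,Lopinot,HP,62,1.37,0.11,0.15,no
males,Lopinot,LP,72,1.43,0.066,0.18,no
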