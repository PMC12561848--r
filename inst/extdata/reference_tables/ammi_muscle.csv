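source,df,ss,ms,f,p,pct
total,119,1854.7651,15.5863,,,
treatment,19,1814.2133,95.4849,235.4638,0,
genotype,3,1580.4493,526.8164,1299.1182,0,85.2102
environment,4,76.8437,19.2109,47.3737,0,4.1430
interaction,12,156.9203,13.0767,32.2468,0,8.4604
IPCA1,6,156.70159,26.11693,64.4038,0,99.8606
IPCA2,4,0.17806,0.04451,0.1098,0.9788,0.1135
residual,2,0.04063,0.02031,,,
error,100,40.55185,0.40552,,,
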