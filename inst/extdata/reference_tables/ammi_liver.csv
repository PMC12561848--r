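source,df,ss,ms,f,p,pct
total,119,68712.453,577.4156,,,
treatment,19,65577.679,3451.4568,110.1022,0,
genotype,3,64644.578,21548.193,687.3921,0,94.0799
environment,4,215.4319,53.858,1.7181,0.1519,0.3135
interaction,12,717.6689,59.8057,1.9078,0.0420,1.0445
IPCA1,6,713.59043,118.93174,3.79395,0.0019,99.4317
IPCA2,4,2.89303,0.72326,0.02307,0.9989,0.4031
residual,2,1.18546,0.59273,,,
error,100,3134.7745,31.34774,,,
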