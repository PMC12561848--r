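source,df,ss,ms,f,p,pct
total,179,112639.63,629.2717,,,
treatment,29,110182.94,3799.4118,231.9842,0,
genotype,5,100879.87,20175.974,1231.903,0,89.5598
environment,4,2258.2031,564.5508,34.4703,0,2.0048
interaction,20,7044.8701,352.2435,21.5073,0,6.2543
IPCA1,8,6894.0632,861.75791,52.6171,0,97.8593
IPCA2,6,113.46768,18.91128,1.15468,0.3338,1.6106
residual,6,37.33918,6.2232,,,
error,150,2456.6838,16.37789,,,
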