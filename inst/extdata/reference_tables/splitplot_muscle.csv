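source,df,ss,ms,f,p
blocks,5,3.31,0.662,,
environment,4,76.8437,19.2109,65.546,<0.001
main_plot_error,20,5.8618,0.2931,,
genotype,3,1580.4493,526.8164,1259.117,<0.001
interaction,12,156.9203,13.0767,31.254,<0.001
sub_plot_error,75,31.3801,0.4184,,
total,119,1854.7651,,,
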