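source,df,ss,ms,f,p
blocks,5,65.5821,13.1164,,
environment,4,2258.2031,564.5508,47.63,<0.001
main_plot_error,20,237.0588,11.8529,,
genotype,5,100879.87,20175.974,1170.82,<0.001
interaction,20,7044.8701,352.2435,20.441,<0.001
sub_plot_error,125,2154.0429,17.2323,,
total,179,112639.63,,,
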