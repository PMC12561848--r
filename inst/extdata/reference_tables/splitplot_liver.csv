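source,df,ss,ms,f,p
blocks,5,106.2773,21.2555,,
environment,4,215.4319,53.858,1.567,0.2217
main_plot_error,20,687.4302,34.3715,,
genotype,3,64644.578,21548.193,690.332,<0.001
interaction,12,717.6689,59.8057,1.916,0.0456
sub_plot_error,75,2341.067,31.2142,,
total,119,68712.453,,,
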