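SNP_A	SNP_B	R2
rs7705526	rs2853677	0.50
rs75691080	rs34978822	0.01
rs75691080	rs73624724	0.01
rs34978822	rs73624724	0.01
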