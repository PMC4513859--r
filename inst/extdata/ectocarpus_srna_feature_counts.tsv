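feature_class	read_count	cumulative_size_bp
exon	3469027	25662441
intron	10424142	81093270
intergenic	7050763	73482052
transposon	8915590	10605262
tRNA	755534	21829
rRNA	7092058	7903
snoRNA	57845	88311
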