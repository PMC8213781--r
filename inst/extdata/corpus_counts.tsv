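category	n
genomes_total	64756
genomes_with_ecis	1249
depleted_pathogen_genomes	18355
depleted_pathogen_with_ecis	0
photorhabdus_genomes	18
photorhabdus_with_ecis	18
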