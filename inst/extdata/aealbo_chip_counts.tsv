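quantity	value
snps_tiled	175396
probes_tiled	404514
tiled_exon	56503
tiled_intron	72305
tiled_intergenic	46588
crosses_samples	152
crosses_recommended	123964
crosses_tested_het_parent	101376
crosses_failed_segregation	2047
wild_samples_passing	243
wild_recommended	115346
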