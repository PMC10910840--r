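category	wgs_n	chip_n
intron	1281482	24387
intergenic	993796	13758
synonymous	384482	14323
non_synonymous	67217	1942
utr5	67744	3642
utr3	64912	3697
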