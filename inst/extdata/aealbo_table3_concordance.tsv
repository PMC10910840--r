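replicate_a	replicate_b	group	type	concordance
1a	1b	1	replicate	99.52
1a	1c	1	replicate	99.31
1b	1c	1	replicate	99.67
2a	2b	2	replicate	98.46
2a	2c	2	replicate	99.33
2b	2c	2	replicate	98.40
3a	3b	3	replicate	99.59
3a	3c	3	replicate	99.59
3b	3c	3	replicate	99.53
4a	4b	4	replicate	99.61
4a	4c	4	replicate	99.52
4b	4c	4	replicate	99.41
1a	2b	NA	random	52.33
3c	2a	NA	random	50.86
1a	4a	NA	random	54.43
3b	1a	NA	random	53.33
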