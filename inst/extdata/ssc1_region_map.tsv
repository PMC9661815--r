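id	chrom	pos	ref	alt
ssc1_snp1	1	309120	A	G
ssc1_snp2	1	477400	A	G
ssc1_snp3	1	705066	A	G
ssc1_snp4	1	712417	A	C
ssc1_snp5	1	768502	A	G
ssc1_snp6	1	771992	A	G
ssc1_snp7	1	887856	A	G
ssc1_snp8	1	1208216	A	G
ssc1_snp9	1	1301402	A	G
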