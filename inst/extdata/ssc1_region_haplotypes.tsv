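haplotype	frequency
AAAAAGAAA	0.02183908
AAAAAGGAA	0.07701149
AAGCGAAAA	0.15632184
AAGCGAAGG	0.23218391
AGAAAGAAA	0.14712644
GAGCGAAAA	0.36551724
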