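exon	first_codon	last_codon
2	1	25
3	26	32
4	33	125
5	126	186
6	187	224
7	225	260
8	261	306
9	307	331
10	332	367
11	368	393
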