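no	id	alleles	pic	ho	gd
1	Chr1_5870698	G/T	0.44	0.83	0.54
2	Chr1_39654059	C/T	0.32	0.43	0.37
3	Chr1_178707315	C/T	0.28	0.36	0.32
4	Chr2_21178624	C/T	0.27	0.36	0.31
5	Chr2_117215365	C/T	0.23	0.28	0.26
6	Chr2_123557945	G/T	0.38	0.65	0.47
7	Chr2_194290628	A/C	0.39	0.5	0.49
8	Chr4_83365171	A/G	0.23	0.24	0.26
9	Chr6_77482863	A/G	0.17	0.12	0.18
10	Chr6_152338984	C/T	0.26	0.31	0.29
11	Chr8_104369549	A/G	0.36	0.59	0.44
12	Chr8_139071641	C/T	0.39	0.44	0.5
13	Chr10_61629141	C/T	0.43	0.72	0.52
14	Chr10_109925494	A/G	0.4	0.44	0.47
15	Chr10_160014631	C/G	0.39	0.32	0.46
16	Chr11_74629953	C/T	0.21	0.23	0.23
17	Chr11_108419904	C/T	0.27	0.24	0.29
18	Chr12_134922457	A/G	0.19	0.22	0.21
19	Chr13_95750187	C/T	0.4	0.63	0.49
20	Chr13_107174655	A/G	0.35	0.38	0.42
21	Chr15_37705498	A/C	0.41	0.55	0.48
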