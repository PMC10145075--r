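pair	iv_id	iv_grade	iv_year	edv_id	edv_grade	edv_year	gs	indisputable
1	FJ115	national	1984	FJ166	provincial	1988	0.9744	1
2	FJ115	national	1984	FJ193	provincial	1998	0.9805	1
3	FJ115	national	1984	SC11	provincial	2015	0.9805	1
4	FJ115	national	1984	SC30	provincial	1985	0.9826	1
5	FJ115	national	1984	SC6	provincial	1989	0.9815	1
6	FJ115	national	1984	SC7	provincial	1989	0.9774	1
7	SC12	provincial	2003	SC10	provincial	2009	0.9703	1
8	SC12	provincial	2003	CQ1	national	2014	0.9774	1
9	SC12	provincial	2003	SC14	provincial	2010	0.9774	1
10	SC12	provincial	2003	SC19	national	2014	0.9754	1
11	AH5	national	1987	SC39	provincial	1989	0.9897	1
12	AH5	national	1987	SC33	provincial	1997	0.9887	1
13	FJ178	national	1985	FJ126	national	2010	0.9344	0
14	FJ114	national	1987	SC25	provincial	2016	0.9805	1
15	ZJ6	national	1987	CQ7	provincial	2001	0.9190	0
16	CQ4	national	1987	CQ10	national	1994	0.9374	0
17	CQ8	national	1994	SC3	national	2014	0.9887	1
18	FJ113	national	2010	SC31	provincial	2018	0.9928	1
19	ZJ18	national	2002	ZJ15	national	2020	0.9815	1
20	HN11	provincial	1987	HN5	national	1994	0.9949	1
21	HN10	provincial	1997	HN8	national	2010	0.9867	1
22	ZJ3	national	1987	HN24	provincial	1987	0.9877	1
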