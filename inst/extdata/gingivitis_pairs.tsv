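index	snp	gene	p	tissue
1	rs1847936	MYT1L	2.29E-06	Artery
2	rs46086588	FYCO1	2.83E-07	Artery
3	rs99117452	ADH6	2.74E-09	Artery
4	rs72121193	FAM86C1	2.50E-14	Artery
5	rs72121193	ALG1L9P	2.33E-06	Artery
6	rs46086588	FYCO1	2.37E-07	Skin
7	rs26844004	RP11-293A21.1	5.45E-07	Skin
8	rs72121193	FAM86C1	2.73E-16	Skin
9	rs72121193	ALG1L9P	2.04E-10	Skin
10	rs72121193	ZNF705E	1.15E-09	Skin
11	rs73832766	MRPL48	2.48E-06	Skin
12	rs46086588	FYCO1	7.30E-08	Neuro
13	rs99117452	ADH5	1.64E-06	Neuro
14	rs72121193	FAM86C1	9.32E-07	Neuro
15	rs72121193	ALG1L9P	1.76E-07	Neuro
16	rs46086588	FYCO1	3.90E-07	Fibroblast
17	rs46330302	CCR1	1.17E-10	Fibroblast
18	rs26844004	RP11-293A21.1	2.29E-06	Fibroblast
19	rs99117452	ADH4	2.07E-07	Fibroblast
20	rs46032426	CITF22-92A6.2	6.02E-07	Fibroblast
21	rs26844004	RP11-293A21.1	2.15E-06	Blood
22	rs99117452	ADH5	2.59E-12	Blood
23	rs72121193	FAM86C1	4.22E-15	Blood
24	rs72121193	NUMA1	4.20E-08	Blood
25	rs47385713	RP11-493L12.6	3.03E-06	Blood
26	rs31232570	EVI2A	5.98E-08	Blood
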