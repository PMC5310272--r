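strain	published_group	published_st	atpA	dnaE	dnaK	fusA	leuA	odhA	rpoB	wild_type	recorded_ancestor	description
ATCC13032	1	1	1	1	1	1	1	1	1	TRUE		type strain (Kyowa Hakko)
ATCC13032B	1	1	1	1	1	1	1	1	1	FALSE		type strain (Bielefeld)
K51	1	1	1	1	1	1	1	1	1	FALSE	ATCC13032	substrain of ATCC13032
MB001	1	1	1	1	1	1	1	1	1	FALSE	ATCC13032	prophage-free reduced-genome variant
ATCC21300	1	1	1	1	1	1	1	1	1	FALSE	ATCC13032	lysine producer
ATCC13869	2	2	1	2	2	4	2	4	4	TRUE		wild-type "B. lactofermentum"
ATCC13870	3	3	4	6	5	5	6	1	1	TRUE		wild-type "C. acetoacidophilum"
ATCC14067	4	4	3	2	4	6	2	2	2	TRUE		wild-type "B. flavum"
ATCC21493	4	5	3	2	4	6	2	5	2	FALSE	ATCC14067	arginine producer
SYPS-062	4	11	3	2	4	6	2	2	5	FALSE		L-serine overproducer
SYPS-062-33a	4	11	3	2	4	6	2	2	5	FALSE	SYPS-062	L-serine overproducer
ATCC15168	4	4	3	2	4	6	2	2	2	FALSE		L-isoleucine producer
R	5	6	5	3	7	3	3	2	1	TRUE		wild type isolated in Japan
AS1.299	6	7	2	5	3	5	4	3	3	TRUE		wild-type "C. pekinense"
B1	7	8	1	2	4	7	9	3	3	TRUE		glutamate producer (617)
B253	7	13	1	2	4	7	9	3	2	FALSE		lysine producer
T6-13	8	9	5	4	6	2	5	3	1	TRUE		wild-type "B. tianjinese"
SCgG1	8	9	5	4	6	2	5	3	1	FALSE		glutamate hyper-producer
SCgG2	8	9	5	4	6	2	5	3	1	FALSE		glutamate hyper-producer
Z188	8	9	5	4	6	2	5	3	1	FALSE		glutamate hyper-producer
S9114	8	9	5	4	6	2	5	3	1	FALSE	T6-13	industrial glutamate producer
AS1.542	8	9	5	4	6	2	5	3	1	TRUE		wild-type "C. crenatum"
MT	8	10	6	4	6	2	5	3	1	FALSE	AS1.542	arginine-producing mutant
SYPA5-5	8	10	6	4	6	2	5	3	1	FALSE	AS1.542	arginine-producing mutant
ATCC21831	9	12	7	7	2	8	8	1	1	FALSE		L-arginine producer (AR0)
AR1	9	12	7	7	2	8	8	1	1	FALSE		L-arginine producer
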