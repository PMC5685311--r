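2	5000000	5012143	ALS2
14	5000000	5012143	ANG
5	5000000	5012143	ARHGEF28
12	5000000	5012143	ATXN2
17	5000000	5012143	CENPV
3	5000000	5012143	CHMP2B
12	6000000	6012143	DAO
2	6000000	6012143	DCTN1
6	5000000	5012143	FIG4
16	5000000	5012143	FUS
17	6000000	6012143	GRN
12	7000000	7012143	HNRNPA1
7	5000000	5012143	HNRNPA2B1
17	7000000	7012143	MAPT
22	5000000	5012143	NEFH
10	5000000	5012143	OPTN
17	8000000	8012143	PFN1
19	5000000	5012143	PNPLA6
12	8000000	8012143	PRPH
9	5000000	5012143	SETX
9	6000000	6012143	SIGMAR1
21	5000000	5012143	SOD1
5	6000000	6012143	SQSTM1
17	9000000	9012143	TAF15
1	5000000	5012143	TARDBP
X	5000000	5012143	UBQLN2
19	6000000	6012143	UNC13A
20	5000000	5012143	VAPB
9	7000000	7012142	VCP
19	7000000	7012142	ABCA7
19	45404000	45416142	APOE
21	27258000	27270142	APP
2	7000000	7012142	BIN1
6	6000000	6012142	CD2AP
19	9000000	9012142	CD33
8	5000000	5012142	CLU
1	6000000	6012142	CR1
5	7000000	7012142	CSF1R
19	10000000	10012142	DNMT1
13	5000000	5012142	ITM2B
11	5000000	5012142	MS4A4E
11	6000000	6012142	MS4A6A
11	7000000	7012142	PICALM
19	11000000	11012142	PLD3
14	6000000	6012142	PSEN1
20	6000000	6012142	PRNP
1	7000000	7012142	PSEN2
11	8000000	8012142	SORL1
6	7000000	7012142	TREM2
19	12000000	12012142	TYROBP
4	5000000	5012142	ADH1C
1	8000000	8012142	ATP13A2
3	6000000	6012142	DNAJC13
3	7000000	7012142	EIF4G1
22	6000000	6012142	FBXO7
4	6000000	6012142	GAK
14	7000000	7012142	GCH1
2	8000000	8012142	GIGYF2
2	9000000	9012142	HTRA2
12	9000000	9012142	LRRK2
16	6000000	6012142	MC1R
2	10000000	10012142	NR4A2
20	7000000	7012142	PANK2
6	8000000	8012142	PARK2
1	9000000	9012142	PARK7
3	8000000	8012142	PARL
1	10000000	10012142	PINK1
22	7000000	7012142	PLA2G6
1	11000000	11012142	PM20D1
1	12000000	12012142	RAB7L1
4	7000000	7012142	SNCA
4	8000000	8012142	UCHL1
16	7000000	7012142	VPS35
16	8000000	8012142	ABCC6
13	6000000	6012142	COL4A1
13	7000000	7012142	COL4A2
10	6000000	6012142	HTRA1
19	13000000	13012142	NOTCH3
20	8000000	8012142	SAMHD1
3	9000000	9012142	TREX1
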