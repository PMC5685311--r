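symbol	alias	chromosomal_location	disease_category	associated_phenotype	inheritance_note
ALS2	.	2q33.1	ALS_FTD	ALS2	AR (HZ), juvenile onset
ANG	.	14q11.2	ALS_FTD	ALS9	ADm, late onset
ARHGEF28	.	5q13.2	ALS_FTD	ALS and FTD	AR (HZ) and ADm, late onset
ATXN2	.	12q24.12	ALS_FTD	ALS13	ADm, late onset
CENPV	.	17p11.2	ALS_FTD	ALS	Genetic association, late onset
CHMP2B	.	3p11.2	ALS_FTD	ALS17, FTD	ADm, late onset
DAO	.	12q24.11	ALS_FTD	ALS, schizophrenia	ADm, late onset
DCTN1	.	2p13.1	ALS_FTD	ALS, HMN7B, Perry syndrome	ADm, late onset
FIG4	.	6q21	ALS_FTD	ALS11, CMT disease, YV syndrome	ADm, late onset; AR (HZ and CH), infantile onset
FUS	.	16p11.2	ALS_FTD	ALS6, FTD, HET4	AR (HZ), ADm, late onset
GRN	.	17q21.31	ALS_FTD	FTD, NCL	ADm, late onset; AR (HZ), juvenile onset
HNRNPA1	.	12q13.13	ALS_FTD	ALS20, IBM with early-onset Paget disease with/without FTD 3	ADm, late onset; ADm, early onset
HNRNPA2B1	.	7p15.2	ALS_FTD	IBM with early-onset Paget disease with/without FTD 2	ADm, early onset
MAPT	STH	17q21.31	ALS_FTD	ALS, FTD with parkinsonism, PD, AD, Pick disease, supranuclear palsy, tauopathy	ADm, late and early onset
NEFH	.	22q12.2	ALS_FTD	ALS1	ADm, late onset
OPTN	.	10p13	ALS_FTD	ALS12, glaucoma	AR (HZ) and AD, early onset
PFN1	.	17p13.2	ALS_FTD	ALS18	ADm, earlier onset
PNPLA6	.	19p13.2	ALS_FTD	Spastic paraplegia, Boucher-Neuhauser syndrome	AR (HZ and CH), early onset
PRPH	.	12q13.12	ALS_FTD	ALS1	ADm, late onset
SETX	.	9q34.13	ALS_FTD	ALS4, spinocerebellar ataxia 1	ADm and AR, juvenile onset
SIGMAR1	.	9p13.3	ALS_FTD	ALS16, FTD	AR (HZ); ADm, early onset
SOD1	.	21q22.11	ALS_FTD	ALS1	AR (HZ and CH), ADm, variable onset
SQSTM1	.	5q35.3	ALS_FTD	Paget disease of bone	ADm, late onset
TAF15	.	17q12	ALS_FTD	Chondrosarcoma	.
TARDBP	.	1p36.22	ALS_FTD	ALS10, FTD	ADm, late onset
UBQLN2	.	Xp11.21	ALS_FTD	ALS15, FTD	X-linked, juvenile and late onset
UNC13A	.	19p13.11	ALS_FTD	ALS	Genetic association, late onset
VAPB	.	20q13.33	ALS_FTD	ALS, spinal muscular atrophy (Finkel type)	ADm, early and late onset
VCP	.	9p13.3	ALS_FTD	ALS14, FTD, IBM with early-onset Paget disease with/without FTD 1	ADm, early onset
ABCA7	.	19p13.3	AD_MCI	AD	Genetic association, late onset
APOE	.	19q13.32	AD_MCI	AD2, lipoprotein glomerulopathy, sea-blue histiocyte disease, macular degeneration	ACD, ADm, AR (HZ and CH), late onset
APP	.	21q21.3	AD_MCI	AD1, cerebral amyloid angiopathy	ADm and AR (HZ), early and late onset
BIN1	.	2q14.3	AD_MCI	AD	Genetic association, late onset
CD2AP	.	6p12.3	AD_MCI	AD	Genetic association, late onset
CD33	.	19q13.41	AD_MCI	AD	Genetic association, late onset
CLU	.	8p21.1	AD_MCI	AD	Genetic association, late onset
CR1	.	1q32.2	AD_MCI	AD	Genetic association, late onset
CSF1R	.	5q32	AD_MCI	HDLS with dementia	ADm, early and late onset
DNMT1	.	19p13.2	AD_MCI	HSN1E with dementia	ADm, early onset dementia
ITM2B	.	13q14.2	AD_MCI	Dementia	ADm, early and late onset
MS4A4E	.	11q12.2	AD_MCI	AD	Genetic association, late onset
MS4A6A	.	11q12.2	AD_MCI	AD	Genetic association, late onset
PICALM	.	11q14.2	AD_MCI	AD	Genetic association, late onset
PLD3	.	19q13.2	AD_MCI	AD19	Genetic association, late onset
PSEN1	.	14q24.2	AD_MCI	AD3, dilated cardiomyopathy, FTD, Pick disease, acne inversa	ADm, early onset
PRNP	.	20p13	AD_MCI	Dementia	ADm, early onset
PSEN2	.	1q32.13	AD_MCI	AD4, dilated cardiomyopathy	ADm, early onset
SORL1	.	11q24.1	AD_MCI	AD	ADm, combined gene burden, late onset
TREM2	.	6p21.1	AD_MCI	AD, Nasu-Hakola disease	Genetic association, late onset
TYROBP	.	19q13.12	AD_MCI	Nasu-Hakola disease	AR (HZ), juvenile onset
ADH1C	.	4q23	PD	PD, alcohol dependence protection	Genetic association, late onset
ATP13A2	PARK9	1p36.13	PD	PD, ceroid lipofuscinosis, dementia	Genetic association, early and late onset
DNAJC13	.	3q22.1	PD	PD	ADm, late onset
EIF4G1	.	3q27.1	PD	PD18	ADm, late onset
FBXO7	.	22q12.3	PD	PD15	AR (HZ and CH), early onset
GAK	.	4p16.3	PD	PD	Genetic association, late onset
GCH1	.	14q22.2	PD	PD, dystonia	Genetic association, early onset
GIGYF2	.	2q37.1	PD	PD11	Genetic association, early and late onset
HTRA2	.	2p13.1	PD	PD13	ADm and genetic association, early and late onset
LRRK2	.	12q12	PD	PD8	ADm and genetic association, early and late onset
MC1R	.	16q24.3	PD	PD; melanoma, UV-induced skin damage	Genetic association, late onset
NR4A2	.	2q24.1	PD	PD	Genetic association, late onset
PANK2	.	20p13	PD	Neurodegeneration	AR (HZ and CH), early onset
PARK2	PRKN	6q26	PD	PD2	AR (HZ and CH), juvenile onset; heterozygotes late onset
PARK7	DJ1	1p36.23	PD	PD7	AR (HZ and CH), early onset
PARL	.	3q27.1	PD	PD (mechanistic candidate)	.
PINK1	.	1p36.12	PD	PD6	AR (HZ and CH), ADm, early onset
PLA2G6	.	22q13.1	PD	PD14, NBIA2A, NBIA2B	AR (HZ and CH), early and late onset
PM20D1	.	1q32	PD	PD16	Genetic association, late onset
RAB7L1	.	1q32.1	PD	PD	Genetic association, late onset
SNCA	.	4q22.1	PD	PD1, PD4, LBD	ADm, early onset
UCHL1	.	4p13	PD	PD5, neurodegeneration with optic atrophy	ADm, AR (HZ), juvenile onset
VPS35	.	16q11.2	PD	PD17	ADm, early and late onset
ABCC6	.	16p13.11	VCI	Arterial calcification; pseudoxanthoma elasticum	AR (HZ), infantile onset; AR; ADm
COL4A1	.	13q34	VCI	Angiopathy, brain small vessel disease, porencephaly 1, ICH susceptibility	ADm, infantile onset
COL4A2	.	13q34	VCI	Porencephaly 2, ICH susceptibility	ADm, infantile onset
HTRA1	.	10q26.13	VCI	CARASIL syndrome, macular degeneration	AR (HZ), early onset
NOTCH3	.	19p13.12	VCI	Infantile myofibromatosis 2, CADASIL	ADm, early onset
SAMHD1	.	20q11.23	VCI	Aicardi-Goutieres syndrome 5, chilblain lupus 2	AR (HZ and CH), AD, infantile onset
TREX1	.	3p21.31	VCI	Aicardi-Goutieres syndrome 1, chilblain lupus, retinal vasculopathy with cerebral leukodystrophy	AR (HZ and CH), juvenile onset; AD
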