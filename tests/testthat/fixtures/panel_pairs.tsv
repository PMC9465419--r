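signature	row	gene_a	gene_b	symbol_a	symbol_b
NE-signature	1	3800	2920	KIF5C	CXCL2
NE-signature	2	284339	5029	TMEM145	P2RY2
NE-signature	3	3642	7177	INSM1	TPSAB1
NE-signature	4	94032	9424	CAMK2N2	KCNK6
NE-signature	5	54839	1969	LRRC49	EPHA2
NE-signature	6	1951	166929	CELSR3	SGMS2
NE-signature	7	116442	1308	RAB39B	COL17A1
NE-signature	8	97	10413	ACYP1	YAP1
NE-signature	9	134111	3694	UBE2QL1	ITGB6
NE-signature	10	5798	374	PTPRN	AREG
NE-signature	11	2781	5625	GNAZ	PRODH
NE-signature	12	284424	8796	MIR7-3HG	SCEL
NE-signature	13	50861	79098	STMN3	C1orf116
NE-signature	14	6456	389376	SH3GL2	SFTA2
NE-signature	15	201161	84674	CENPV	CARD6
NE-signature	16	9705	153769	ST18	SH3RF2
NE-signature	17	5865	3868	RAB3B	KRT16
NE-signature	18	4897	56649	NRCAM	TMPRSS4
NE-signature	19	84707	8743	BEX2	TNFSF10
NE-signature	20	6328	11254	SCN3A	SLC6A14
NE-signature	21	134548	59272	SOWAHA	ACE2
NE-signature	22	23089	4680	PEG10	CEACAM6
CARCI-signature	1	4675	11065	NAP1L3	UBE2C
CARCI-signature	2	114786	10403	XKR4	NDC80
CARCI-signature	3	9514	6790	GAL3ST1	AURKA
CARCI-signature	4	18	113130	ABAT	CDCA5
CARCI-signature	5	1036	10635	CDO1	RAD51AP1
CARCI-signature	6	1496	83540	CTNNA2	NUF2
CARCI-signature	7	100286909	10457	LOC100286909	GPNMB
CARCI-signature	8	163255	79000	ZNF540	AUNIP
CARCI-signature	9	10903	29128	MTMR11	UHRF1
CARCI-signature	10	257396	144455	LOC257396	E2F7
CARCI-signature	11	158572	4175	USP27X-AS1	MCM6
CARCI-signature	12	3697	699	ITIH1	BUB1
CARCI-signature	13	148641	990	SLC35F3	CDC6
CARCI-signature	14	140597	5984	TCEAL2	RFC4
CARCI-signature	15	4674	822	NAP1L2	CAPG
CARCI-signature	16	26149	6850	ZNF658	SYK
CARCI-signature	17	387856	55789	CCDC184	DEPDC1B
CARCI-signature	18	8786	55010	RGS11	PARPBP
CARCI-signature	19	100130360	6502	LOC100130360	SKP2
CARCI-signature	20	645249	1063	MNX1-AS1	CENPF
CARCI-signature	21	51310	2146	SLC22A17	EZH2
CARCI-signature	22	6861	79733	SYT5	E2F8
CARCI-signature	23	9378	9928	NRXN1	KIF14
CARCI-signature	24	57213	7272	SPRYD7	TTK
CARCI-signature	25	5502	3815	PPP1R1A	KIT
CARCI-signature	26	23040	26047	MYT1L	CNTNAP2
CARCI-signature	27	727	8140	C5	SLC7A5
CARCI-signature	28	117153	80078	MIA2	LCAL1
CARCI-signature	29	401190	4246	RGS7BP	SCGB2A1
CARCI-signature	30	222546	5166	RFX6	PDK4
SCLC-signature	1	23544	283	SEZ6L	ANG
SCLC-signature	2	85300	100505490	ATCAY	LOC100505490
SCLC-signature	3	257068	2184	PLCXD2	FAH
SCLC-signature	4	7552	140809	ZNF711	SRXN1
SCLC-signature	5	138948	54795	DBH-AS1	TRPM4
SCLC-signature	6	3746	55286	KCNC1	C4orf19
SCLC-signature	7	284219	84561	LOC284219	SLC12A8
SCLC-signature	8	64105	55974	CENPK	SLC50A1
SCLC-signature	9	56896	12	DPYSL5	SERPINA3
SCLC-signature	10	4781	4853	NFIB	NOTCH2
SCLC-signature	11	9024	10257	BRSK2	ABCC4
SCLC-signature	12	29767	6286	TMOD2	S100P
SCLC-signature	13	84620	84962	ST6GAL2	AJUBA
SCLC-signature	14	1995	100	ELAVL3	ADA
SCLC-signature	15	112609	51205	MRAP2	ACP6
SCLC-signature	16	286151	2948	FBXO43	GSTM4
SCLC-signature	17	134121	30848	C5orf49	CTAG2
SCLC-signature	18	199699	57546	DAND5	PDP2
SCLC-signature	19	145581	121355	LRFN5	GTSF1
SCLC-signature	20	284244	23704	LOC284244	KCNE4
SCLC-signature	21	259266	84221	ASPM	SPATC1L
SCLC-signature	22	773	84419	CACNA1A	C15orf48
SCLC-signature	23	388341	7078	LRRC75A	TIMP3
SCLC-signature	24	84623	117854	KIRREL3	TRIM6
SCLC-signature	25	100130097	4199	KIF28P	ME1
SCLC-signature	26	4005	5118	LMO2	PCOLCE
SCLC-signature	27	53616	4100	ADAM22	MAGEA1
SCLC-signature	28	219287	563	AMER2	AZGP1
SCLC-signature	29	375704	55076	ENHO	TMEM45A
SCLC-signature	30	9515	222171	STXBP5L	PRR15
SCLC-signature	31	1630	79679	DCC	VTCN1
SCLC-signature	32	56961	337876	SHD	CHSY3
SCLC-signature	33	100130705	4973	ATP6V1FNB	OLR1
SCLC-signature	34	5100	4600	PCDH8	MX2
SCLC-signature	35	2259	56667	FGF14	MUC13
SCLC-signature	36	26040	8870	SETBP1	IER3
SCLC-signature	37	388228	1829	SBK1	DSG2
SCLC-signature	38	1917	25878	EEF1A2	MXRA5
SCLC-signature	39	285888	5992	CNPY1	RFX4
SCLC-signature	40	3670	1124	ISL1	CHN2
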