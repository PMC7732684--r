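module_id	grid_position	n_transcripts	annotation	representative_genes
M15.84	A35-1	20	Cytokines/chemokines	S100P, TLR2, MAPK14, FCAR
M13.16	A35-2	39	Cytokines/chemokines	BTNL8, CR1, FFAR2, FPR2, TLR6, ALPK1
M13.1	A35-3	137	Inflammation (innate immune response activation)	PYCARD, CLEC4A, SYK, CD300A, PRKCD, PELI1, LILRA2, MYD88, HSPA1B
M15.37	A35-4	33	Inflammation (leukocyte migration)	LAT2, SLC7A8, IL1B, FPR2, SLC16A3, GPSM3
M15.113	A35-5	16	Inflammation	SOCS3, RAB20, MAPK14, BMX, RASGRP4
M12.10	A35-6	53	Inflammation (neutrophil degranulation)	CRISPLD2, ALOX5, LAMP2, RAB24, ITGAX, TIMP2, SIRPA, RNASE3, LILRB3, IGF2R
M13.12	A35-7	55	Innate immunity, myeloid cells, inflammasomes	AIM2, TLR5, SIGLEC5, IL18RAP, IL18R1, S100A12, NLRC4, IRAK3, TNFAIP6, CLEC4D, LILRA5, FCGR1A, FCGR1B
M15.105	A35-8	16	Inflammation (myeloid cells, arginase pathway)	MAP3K3, TYROBP, PSMB3, LILRB2
M15.109	A35-9	17	Inflammation (defense response, leukocyte migration)	IL1RN, IL6R, TNFRSF10B, CR1, TLR8, FCGR2A
M13.22	A35-10	65	Neutrophils (response to LPS)	AKIRIN2, SLC11A1, C5AR1, LY96, TRIB1, LITAF, IFNAR1
M14.28	A35-11	20	Neutrophils (neutrophil degranulation)	BST1, MMP25, SERPINA1, FCER1G, ITGAM, SLC2A3, LILRA2, OSCAR
M15.26	A35-12	38	Neutrophils (activation, exocytosis)	PREX1, CEACAM3, ATP8B4, PLAUR, RAB27A, HPSE, SIRPB1
M14.65	A35-13	15	Monocyte (host defense)	ITGB2, CYBA, CD14, GNS, RAB7A, IFNGR2
M16.79	A35-14	27	Protein synthesis (secretion)	PYCARD, CNN2, FAM49B, RHOT1, DNAJC5, GAPDH, MCU, LILRA5
M16.98	A35-15	18	TBD	IL22, VDR, KREMEN1, LOXL3, ADORA2B, MAK, TIFA
M13.3	A35-16	100	TBD (response to stress)?	ERO1A, MAP3K2, G6PD, GADD45A, EDEM2, GBA, WIPI1
M14.7	A35-17	31	TBD	MFN2, JAK2, BATF, TFE3, CPEB3
M14.74	A35-18	14	TBD	MOSPD2, CD58, CKLF, CD53, TLE4, RNASEL
M15.43	A35-19	30	TBD (protein secretion)?	RCN3, COP1, CARD16, CLEC4E, CAMK2G
M15.78	A35-20	20	TBD (signal transduction)?	CSF3R, IL4R, SEMA4B, MKNK1, CREBRF, GPAT3, REM2
M15.81	A35-21	20	TBD (neutrophil degranulation)	PKM, GAA, ALDOA, AGPAT2
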