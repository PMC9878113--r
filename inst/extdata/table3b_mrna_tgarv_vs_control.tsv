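feature_id	fold_change	adjusted_p	regulation
YOD1	0.27	0.0321	Lower
PDGFC	0.36	0.0373	Lower
TRIM58	0.38	0.0340	Lower
TENT5C	0.40	0.0343	Lower
XK	0.40	0.0456	Lower
TMOD1	0.40	0.0256	Lower
JAZF1	0.40	0.0455	Lower
RNF11	0.40	0.0346	Lower
SNCA	0.40	0.0370	Lower
FOXO3	0.41	0.0275	Lower
GCLC	0.41	0.0403	Lower
KAT2B	0.42	0.0414	Lower
FURIN	0.43	0.0348	Lower
TPM1	0.44	0.0330	Lower
RHOBTB1	0.45	0.0460	Lower
SLC7A5	0.45	0.0450	Lower
PIP5K1B	0.45	0.0368	Lower
CTNNAL1	0.46	0.0345	Lower
RAP2A	0.46	0.0439	Lower
CALD1	0.47	0.0451	Lower
FNBP1L	0.47	0.0321	Lower
ARHGAP6	0.48	0.0371	Lower
CREG1	0.49	0.0362	Lower
TBCEL	0.50	0.0445	Lower
GCNT1	0.50	0.0320	Lower
GSPT1	0.50	0.0401	Lower
RIOK3	0.50	0.0445	Lower
PDCD10	0.50	0.0374	Lower
ABCB10	0.50	0.0458	Lower
TTC7B	0.51	0.0326	Lower
DNAJC6	0.51	0.0340	Lower
ADIPOR1	0.51	0.0346	Lower
RGS1	0.52	0.0449	Lower
NRP1	0.52	0.0358	Lower
TMC5	0.52	0.0167	Lower
BNIP3L	0.52	0.0322	Lower
RIPOR3	0.52	0.0118	Lower
STOM	0.53	0.0341	Lower
DNM3	0.53	0.0349	Lower
NIPSNAP3A	0.53	0.0432	Lower
F13A1	0.53	0.0422	Lower
FAM104A	0.53	0.0313	Lower
TFDP1	0.53	0.0372	Lower
XYLT1	0.53	0.0451	Lower
CLIC2	0.53	0.0117	Lower
RHCE	0.53	0.0420	Lower
MKRN1	0.53	0.0373	Lower
TUBB1	0.54	0.0463	Lower
PTPRF	0.54	0.0192	Lower
SRXN1	0.54	0.0158	Lower
DAB2	0.54	0.0461	Lower
SFRP2	0.54	0.0453	Lower
SLC25A37	0.54	0.0433	Lower
PIP4K2A	0.55	0.0179	Lower
GP6	0.56	0.0413	Lower
GUCY1B1	0.56	0.0473	Lower
HRH4	0.56	0.0422	Lower
EPB41	0.57	0.0372	Lower
VEGFC	0.57	0.0438	Lower
HEXIM1	0.57	0.0385	Lower
HNMT	0.57	0.0444	Lower
DACH1	0.58	0.0357	Lower
GAPT	0.58	0.0363	Lower
RPIA	0.58	0.0412	Lower
MPP1	0.58	0.0333	Lower
COPS2	0.58	0.0458	Lower
CHMP4B	0.59	0.0323	Lower
P2RY12	0.59	0.0460	Lower
FAM117A	0.59	0.0458	Lower
BMP6	0.59	0.0370	Lower
DCAF6	0.59	0.0242	Lower
MPL	0.60	0.0446	Lower
CA8	0.60	0.0410	Lower
GOLM1	0.60	0.0473	Lower
ACPP	0.60	0.0317	Lower
STON1	0.60	0.0458	Lower
RNF10	0.60	0.0373	Lower
BHLHE40	0.61	0.0370	Lower
SNX3	0.61	0.0411	Lower
SPTA1	0.61	0.0348	Lower
WNK1	0.61	0.0421	Lower
CLEC5A	0.61	0.0403	Lower
RAB27B	0.61	0.0442	Lower
KLRB1	0.61	0.0459	Lower
ODC1	0.62	0.0345	Lower
OPTN	0.62	0.0453	Lower
ATP6V0C	0.62	0.0358	Lower
TAL1	0.62	0.0460	Lower
DHX29	0.62	0.0460	Lower
ZNF469	0.62	0.0345	Lower
UBE2E3	0.63	0.0459	Lower
VCL	0.63	0.0359	Lower
HK1	0.63	0.0366	Lower
KIF1B	0.63	0.0482	Lower
LRP12	0.63	0.0440	Lower
PCDH9	0.64	0.0464	Lower
TFPI	0.64	0.0459	Lower
LTBP1	0.64	0.0342	Lower
VLDLR	0.64	0.0451	Lower
BMP2K	0.65	0.0375	Lower
RNF14	0.65	0.0418	Lower
SELENOK	0.65	0.0334	Lower
C2orf76	0.66	0.0310	Lower
SLC6A4	0.66	0.0456	Lower
CTNNA1	0.66	0.0461	Lower
EPHX2	2.21	0.0336	Higher
CD8B2	2.15	0.0146	Higher
RHPN1	2.10	0.0157	Higher
KLK1	2.04	0.0349	Higher
PLEKHB1	1.95	0.0326	Higher
TCF7	1.95	0.0419	Higher
CD248	1.93	0.0135	Higher
FHIT	1.91	0.0420	Higher
CD8B	1.90	0.0457	Higher
CCR10	1.81	0.0451	Higher
C12orf57	1.81	0.0411	Higher
NPM3	1.78	0.0180	Higher
PCSK4	1.76	0.0114	Higher
C1QTNF6	1.75	0.0437	Higher
IQCN	1.74	0.0365	Higher
ASIC1	1.74	0.0141	Higher
FXYD2	1.73	0.0401	Higher
TMIGD2	1.72	0.0370	Higher
NRCAM	1.72	0.0317	Higher
HIST1H1D	1.71	0.0375	Higher
NOSIP	1.69	0.0326	Higher
TLE2	1.66	0.0356	Higher
AMIGO1	1.66	0.0459	Higher
SYNE4	1.66	0.0349	Higher
PTPRCAP	1.64	0.0340	Higher
SELENOM	1.64	0.0458	Higher
SOX8	1.64	0.0457	Higher
KLHL34	1.63	0.0209	Higher
NPY4R	1.62	0.0404	Higher
GSDMB	1.61	0.0444	Higher
LIG1	1.61	0.0110	Higher
FAM174B	1.60	0.0350	Higher
SLC27A5	1.60	0.0430	Higher
RPL36	1.60	0.0255	Higher
HPDL	1.58	0.0460	Higher
SCML4	1.58	0.0255	Higher
CD7	1.57	0.0353	Higher
COL6A1	1.57	0.0373	Higher
VILL	1.56	0.0456	Higher
MYL6B	1.56	0.0454	Higher
MTFP1	1.56	0.0330	Higher
C19orf48	1.55	0.0369	Higher
GPC2	1.54	0.0311	Higher
SFI1	1.54	0.0328	Higher
MRNIP	1.54	0.0124	Higher
CD27	1.54	0.0406	Higher
MST1R	1.53	0.0404	Higher
ZFP90	1.53	0.0441	Higher
TEDC1	1.53	0.0341	Higher
ATP5IF1	1.53	0.0314	Higher
SPEG	1.52	0.0440	Higher
ZNF692	1.52	0.0120	Higher
STMN3	1.52	0.0452	Higher
ZNF444	1.52	0.0115	Higher
TMEM160	1.51	0.0358	Higher
TESPA1	1.51	0.0314	Higher
ADAMTS13	1.51	0.0156	Higher
PBX4	1.51	0.0458	Higher
ATAD3B	1.50	0.0431	Higher
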