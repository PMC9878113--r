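feature_id	fold_change	adjusted_p	regulation
TMOD1	0.47	0.0321	Lower
PRSS33	0.52	0.0270	Lower
SFRP2	0.55	0.0493	Lower
RGS1	0.55	0.0485	Lower
SRXN1	0.55	0.0181	Lower
RHCE	0.56	0.0444	Lower
TFDP1	0.59	0.0298	Lower
DNAJC6	0.59	0.0476	Lower
HRH4	0.59	0.0433	Lower
PTPRF	0.60	0.0286	Lower
NRP1	0.60	0.0466	Lower
RIPOR3	0.60	0.0204	Lower
DACH1	0.61	0.0444	Lower
STOM	0.61	0.0347	Lower
TMC5	0.62	0.0350	Lower
MPP1	0.64	0.0440	Lower
OXER1	0.64	0.0300	Lower
CLEC5A	0.65	0.0218	Lower
LRRN3	2.47	0.0394	Higher
TRABD2A	1.84	0.0448	Higher
CD8B2	1.84	0.0206	Higher
PLEKHB1	1.71	0.0210	Higher
IQCN	1.71	0.0340	Higher
CD248	1.70	0.0306	Higher
IL7R	1.69	0.0449	Higher
TMIGD2	1.66	0.0274	Higher
C1QTNF6	1.62	0.0480	Higher
NRCAM	1.61	0.0357	Higher
ASIC1	1.56	0.0449	Higher
NPM3	1.56	0.0382	Higher
GSDMB	1.56	0.0425	Higher
NOSIP	1.54	0.0362	Higher
PTPRCAP	1.54	0.0237	Higher
PBX4	1.52	0.0203	Higher
OFD1	1.50	0.0209	Higher
SCML4	1.50	0.0278	Higher
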