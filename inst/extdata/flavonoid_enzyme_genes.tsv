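enzyme	gene_id	M_FPKM	N_FPKM	Q_FPKM	log2fc_NvsQ_reported	type_NvsQ
E5.5.1.6	TRIITY_DN8870_c0_g1_i1-A1	40.09	57.31	60.77	0.08	UP
C12RT1	TRIITY_DN13850_c0_g1_i1-A1	6.47	13.35	18.85	0.50	UP
PGT1	TRIITY_DN1011_c0_g1_i5-A1	34.83	60.62	86.63	0.51	UP
PGT1	TRIITY_DN18356_c0_g1_i1-A1	9.92	39.38	71.62	0.86	UP
PGT1	TRIITY_DN18356_c0_g1_i2-A1	8.70	38.21	81.37	1.09	UP
PGT1	TRIITY_DN18663_c0_g1_i2-A1	5.56	18.87	44.13	1.23	UP
PGT1	TRIITY_DN4314_c0_g1_i3-A1	26.71	51.52	81.98	0.67	UP
PGT1	TRIITY_DN4314_c0_g2_i2-A1	6.80	20.16	31.40	0.64	UP
PGT1	TRIITY_DN5579_c0_g1_i1-A1	23.16	64.69	132.54	1.03	UP
PGT1	TRIITY_DN6182_c0_g1_i1-A1	5.94	31.04	59.57	0.94	UP
PGT1	TRIITY_DN6182_c0_g1_i3-A1	5.36	18.55	42.34	1.19	UP
FLS	TRIITY_DN14637_c0_g2_i1-A1	9.45	18.83	23.55	0.32	UP
FLS	TRIITY_DN8661_c0_g1_i1-A1	10.63	43.70	38.56	-0.18	DOWN
DFR	TRIITY_DN26672_c0_g1_i1-A1	11.70	37.19	66.67	0.84	UP
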