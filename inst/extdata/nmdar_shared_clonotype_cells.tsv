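sequence_id	patient_id	cell_id	locus	v_call	d_call	j_call	junction	junction_aa	cdr3_aa	productive
PA21_ct1_H	PA21	PA21_ct1	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA21_ct1_L	PA21	PA21_ct1	IGL	IGLV1-44*01		IGLJ3*02	TGTGCCGCCTGGGACGACTCCCTGAACGGCCCCGTGTTC	CAAWDDSLNGPVF	AAWDDSLNGPV	T
PA22_ct1_H	PA22	PA22_ct1	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA22_ct1_L	PA22	PA22_ct1	IGL	IGLV1-44*01		IGLJ3*02	TGTGCCGCCTGGGACGACTCCCTGAACGGCCCCGTGTTC	CAAWDDSLNGPVF	AAWDDSLNGPV	T
PA23_ct1_H	PA23	PA23_ct1	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA23_ct1_L	PA23	PA23_ct1	IGL	IGLV1-44*01		IGLJ3*02	TGTGCCGCCTGGGACGACTCCCTGAACGGCCCCGTGTTC	CAAWDDSLNGPVF	AAWDDSLNGPV	T
PA25_ct1_H	PA25	PA25_ct1	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA25_ct1_L	PA25	PA25_ct1	IGL	IGLV1-44*01		IGLJ3*02	TGTGCCGCCTGGGACGACTCCCTGAACGGCCCCGTGTTC	CAAWDDSLNGPVF	AAWDDSLNGPV	T
PA29_ct1_H	PA29	PA29_ct1	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA29_ct1_L	PA29	PA29_ct1	IGL	IGLV1-44*01		IGLJ3*02	TGTGCCGCCTGGGACGACTCCCTGAACGGCCCCGTGTTC	CAAWDDSLNGPVF	AAWDDSLNGPV	T
PA21_ct2_H	PA21	PA21_ct2	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA21_ct2_L	PA21	PA21_ct2	IGL	IGLV1-40*01,IGLV1-40*02		IGLJ3*02	TGTCAGTCCTACGACCGGTCCCTGTCCGGCTACTGGGTGTTC	CQSYDRSLSGYWVF	QSYDRSLSGYWV	T
PA22_ct2_H	PA22	PA22_ct2	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA22_ct2_L	PA22	PA22_ct2	IGL	IGLV1-40*01,IGLV1-40*02		IGLJ3*02	TGTCAGTCCTACGACCGGTCCCTGTCCGGCTACTGGGTGTTC	CQSYDRSLSGYWVF	QSYDRSLSGYWV	T
PA23_ct2_H	PA23	PA23_ct2	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA23_ct2_L	PA23	PA23_ct2	IGL	IGLV1-40*01,IGLV1-40*02		IGLJ3*02	TGTCAGTCCTACGACCGGTCCCTGTCCGGCTACTGGGTGTTC	CQSYDRSLSGYWVF	QSYDRSLSGYWV	T
PA8_ct3_H	PA8	PA8_ct3	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA8_ct3_L	PA8	PA8_ct3	IGL	IGLV1-44*01		IGLJ2*01,IGLJ3*01	TGTGCCGCCTGGGACGACTCCCTGACCGGCGTGGTGTTC	CAAWDDSLTGVVF	AAWDDSLTGVV	T
PA22_ct3_H	PA22	PA22_ct3	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA22_ct3_L	PA22	PA22_ct3	IGL	IGLV1-44*01		IGLJ2*01,IGLJ3*01	TGTGCCGCCTGGGACGACTCCCTGACCGGCGTGGTGTTC	CAAWDDSLTGVVF	AAWDDSLTGVV	T
PA30_ct3_H	PA30	PA30_ct3	IGH	IGHV1-18*04	IGHD1-26*01,IGHD2-2*03,IGHD2-8*01	IGHJ3*02	TGTGCCCGGGTGGGCTCCAAGTACGGCTTCGAGACCTTCGACATCTGG	CARVGSKYGFETFDIW	ARVGSKYGFETFDI	T
PA30_ct3_L	PA30	PA30_ct3	IGL	IGLV1-44*01		IGLJ2*01,IGLJ3*01	TGTGCCGCCTGGGACGACTCCCTGACCGGCGTGGTGTTC	CAAWDDSLTGVVF	AAWDDSLTGVV	T
PA11_ct4_H	PA11	PA11_ct4	IGH	IGHV4-39*01	IGHD6-6*01	IGHJ4*02	TGTGCCCGGCGGTCCTCCGGCGTGCGGATCGCCGCCCGGCGGCCCTTCGACTGTTGG	CARRSSGVRIAARRPFDCW	ARRSSGVRIAARRPFDC	T
PA11_ct4_L	PA11	PA11_ct4	IGL	IGLV2-11*01		IGLJ3*02	TGTTCCTCCTACGTGCGGGCCTGGGTGTTC	CSSYVRAWVF	SSYVRAWV	T
PA31_ct4_H	PA31	PA31_ct4	IGH	IGHV4-39*01	IGHD6-6*01	IGHJ4*02	TGTGCCCGGCGGTCCTCCGGCGTGCGGATCGCCGCCCGGCGGCCCTTCGACTGTTGG	CARRSSGVRIAARRPFDCW	ARRSSGVRIAARRPFDC	T
PA31_ct4_L	PA31	PA31_ct4	IGL	IGLV2-11*01		IGLJ3*02	TGTTCCTCCTACGTGCGGGCCTGGGTGTTC	CSSYVRAWVF	SSYVRAWV	T
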