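allele_id	locus	segment_type	cys_codon_start	j_motif_start	reading_frame_offset
IGHV1-18*04	IGH	V	289		
IGHV1-69*01	IGH	V	289		
IGHV3-23*01	IGH	V	289		
IGHV4-39*01	IGH	V	289		
IGHV5-51*01	IGH	V	289		
IGHD1-26*01	IGH	D			
IGHD2-2*03	IGH	D			
IGHD2-8*01	IGH	D			
IGHD3-10*01	IGH	D			
IGHD6-6*01	IGH	D			
IGHJ3*02	IGH	J		22	0
IGHJ4*02	IGH	J		22	0
IGHJ5*02	IGH	J		22	0
IGHJ6*02	IGH	J		22	0
IGKV1-39*01	IGK	V	289		
IGKV2-28*01	IGK	V	289		
IGKV3-20*01	IGK	V	289		
IGKV4-1*01	IGK	V	289		
IGKJ1*01	IGK	J		22	0
IGKJ2*01	IGK	J		22	0
IGKJ4*01	IGK	J		22	0
IGLV1-40*01	IGL	V	289		
IGLV1-40*02	IGL	V	289		
IGLV1-44*01	IGL	V	289		
IGLV2-11*01	IGL	V	289		
IGLV2-14*01	IGL	V	289		
IGLJ1*01	IGL	J		22	0
IGLJ2*01	IGL	J		22	0
IGLJ3*01	IGL	J		22	0
IGLJ3*02	IGL	J		22	0
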