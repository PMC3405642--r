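# four illustrative individuals, one per study class of interest
sample	locus	allele
case_AD	709	A
case_AD	4833	G
case_AD	5108	C
case_AD	5601	T
case_AD	7600	A
case_AD	9377	G
case_AD	9575	A
case_AD	13563	G
case_AD	14569	A
case_AD	16362	C
case_AD	16519	C
case_PD	204	C
case_PD	709	A
case_PD	1598	A
case_PD	8584	A
case_PD	9950	C
case_PD	12358	G
case_PD	12361	G
case_PD	15223	T
case_PD	15927	A
case_PD	16140	C
case_T2D	194	T
case_T2D	1382	C
case_T2D	3010	A
case_T2D	4883	T
case_T2D	5178	A
case_T2D	8020	A
case_T2D	8414	T
case_T2D	8964	T
case_T2D	9824	A
case_T2D	14668	T
case_T2D	16519	C
case_CENT	199	C
case_CENT	1382	C
case_CENT	3010	A
case_CENT	4883	T
case_CENT	5178	A
case_CENT	8020	A
case_CENT	8414	T
case_CENT	8964	T
case_CENT	9824	A
case_CENT	10104	T
case_CENT	14668	T
case_CENT	16362	C
case_CENT	16519	C
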