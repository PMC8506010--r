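chrM	0	576	D-loop	0	+
chrM	576	647	tRNA-Phe	0	+
chrM	647	1601	12S rRNA	0	+
chrM	1601	1670	tRNA-Val	0	+
chrM	1670	3229	16S rRNA	0	+
chrM	3229	3304	tRNA-Leu(UUR)	0	+
chrM	3306	4262	ND1	0	+
chrM	4262	4331	tRNA-Ile	0	+
chrM	4328	4400	tRNA-Gln	0	-
chrM	4401	4469	tRNA-Met	0	+
chrM	4469	5511	ND2	0	+
chrM	5511	5579	tRNA-Trp	0	+
chrM	5586	5655	tRNA-Ala	0	-
chrM	5656	5729	tRNA-Asn	0	-
chrM	5760	5826	tRNA-Cys	0	-
chrM	5825	5891	tRNA-Tyr	0	-
chrM	5903	7445	COI	0	+
chrM	7445	7514	tRNA-Ser(UCN)	0	-
chrM	7517	7585	tRNA-Asp	0	+
chrM	7585	8269	COII	0	+
chrM	8294	8364	tRNA-Lys	0	+
chrM	8365	8572	ATPase8	0	+
chrM	8526	9207	ATPase6	0	+
chrM	9206	9990	COIII	0	+
chrM	9990	10058	tRNA-Gly	0	+
chrM	10058	10404	ND3	0	+
chrM	10404	10469	tRNA-Arg	0	+
chrM	10469	10766	ND4L	0	+
chrM	10759	12137	ND4	0	+
chrM	12137	12206	tRNA-His	0	+
chrM	12206	12265	tRNA-Ser(AGY)	0	+
chrM	12265	12336	tRNA-Leu(CUN)	0	+
chrM	12336	14148	ND5	0	+
chrM	14148	14673	ND6	0	-
chrM	14673	14742	tRNA-Glu	0	-
chrM	14746	15887	Cyt b	0	+
chrM	15887	15953	tRNA-Thr	0	+
chrM	15955	16023	tRNA-Pro	0	-
chrM	16023	16569	D-loop	0	+
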