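region	start	end	class
D-loop	16024	16569	dloop
D-loop	1	576	dloop
HVR_I	16024	16383	sub
MT-TF	577	647	tRNA
MT-RNR1	648	1601	rRNA
MT-TV	1602	1670	tRNA
MT-RNR2	1671	3229	rRNA
MT-TL1	3230	3304	tRNA
MT-ND1	3307	4262	gene
MT-TI	4263	4331	tRNA
MT-TQ	4329	4400	tRNA
MT-TM	4402	4469	tRNA
MT-ND2	4470	5511	gene
MT-TW	5512	5579	tRNA
MT-TA	5587	5655	tRNA
MT-TN	5657	5729	tRNA
MT-TC	5761	5826	tRNA
MT-TY	5826	5891	tRNA
MT-CO1	5904	7445	gene
MT-TS1	7446	7514	tRNA
MT-TD	7518	7585	tRNA
MT-CO2	7586	8269	gene
MT-TK	8295	8364	tRNA
MT-ATP8	8366	8572	gene
MT-ATP6	8527	9207	gene
MT-CO3	9207	9990	gene
MT-TG	9991	10058	tRNA
MT-ND3	10059	10404	gene
MT-TR	10405	10469	tRNA
MT-ND4L	10470	10766	gene
MT-ND4	10760	12137	gene
MT-TH	12138	12206	tRNA
MT-TS2	12207	12265	tRNA
MT-TL2	12266	12336	tRNA
MT-ND5	12337	14148	gene
MT-ND6	14149	14673	gene
MT-TE	14674	14742	tRNA
MT-CYB	14747	15887	gene
MT-TT	15888	15953	tRNA
MT-TP	15956	16023	tRNA
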