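name	start	end	strand	kind	wrap
D-loop	16024	576	heavy	control	1
tRNA-Phe	577	647	heavy	tRNA	0
12S rRNA	648	1601	heavy	rRNA	0
tRNA-Val	1602	1670	heavy	tRNA	0
16S rRNA	1671	3229	heavy	rRNA	0
tRNA-Leu(UUR)	3230	3304	heavy	tRNA	0
ND1	3307	4262	heavy	protein	0
tRNA-Ile	4263	4331	heavy	tRNA	0
tRNA-Gln	4329	4400	light	tRNA	0
tRNA-Met	4402	4469	heavy	tRNA	0
ND2	4470	5511	heavy	protein	0
tRNA-Trp	5512	5579	heavy	tRNA	0
tRNA-Ala	5587	5655	light	tRNA	0
tRNA-Asn	5657	5729	light	tRNA	0
tRNA-Cys	5761	5826	light	tRNA	0
tRNA-Tyr	5826	5891	light	tRNA	0
OL	5721	5798	light	noncoding	0
COX1	5904	7445	heavy	protein	0
tRNA-Ser(UCN)	7446	7514	light	tRNA	0
tRNA-Asp	7518	7585	heavy	tRNA	0
COX2	7586	8269	heavy	protein	0
tRNA-Lys	8295	8364	heavy	tRNA	0
ATP8	8366	8572	heavy	protein	0
ATP6	8527	9207	heavy	protein	0
COX3	9207	9990	heavy	protein	0
tRNA-Gly	9991	10058	heavy	tRNA	0
ND3	10059	10404	heavy	protein	0
tRNA-Arg	10405	10469	heavy	tRNA	0
ND4L	10470	10766	heavy	protein	0
ND4	10760	12137	heavy	protein	0
tRNA-His	12138	12206	heavy	tRNA	0
tRNA-Ser(AGY)	12207	12265	heavy	tRNA	0
tRNA-Leu(CUN)	12266	12336	heavy	tRNA	0
ND5	12337	14148	heavy	protein	0
ND6	14149	14673	light	protein	0
tRNA-Glu	14674	14742	light	tRNA	0
CYTB	14747	15887	heavy	protein	0
tRNA-Thr	15888	15953	heavy	tRNA	0
tRNA-Pro	15956	16023	light	tRNA	0
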