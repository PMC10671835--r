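name	start	end	category
D-loop	16024	576	control
tRNA-F	577	647	tRNA
RNR1	648	1601	rRNA
tRNA-V	1602	1670	tRNA
RNR2	1671	3229	rRNA
tRNA-L1	3230	3304	tRNA
ND1	3307	4262	CDS
tRNA-I	4263	4331	tRNA
tRNA-Q	4332	4400	tRNA
tRNA-M	4402	4469	tRNA
ND2	4470	5511	CDS
tRNA-W	5512	5579	tRNA
CO1	5904	7445	CDS
tRNA-S1	7446	7514	tRNA
tRNA-D	7518	7585	tRNA
CO2	7586	8269	CDS
tRNA-K	8295	8364	tRNA
ATP8	8366	8572	CDS
ATP6	8527	9207	CDS
CO3	9208	9990	CDS
tRNA-G	9991	10058	tRNA
ND3	10059	10404	CDS
tRNA-R	10405	10469	tRNA
ND4	10470	12137	CDS
tRNA-H	12138	12206	tRNA
tRNA-S2	12207	12265	tRNA
tRNA-L2	12266	12336	tRNA
ND5	12337	14148	CDS
ND6	14149	14673	CDS
tRNA-E	14674	14742	tRNA
CYB	14747	15887	CDS
tRNA-T	15888	15953	tRNA
tRNA-P	15956	16023	tRNA
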