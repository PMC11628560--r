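name	class	start	end	sub_region
D-loop	D-loop	16026	578	
7S	D-loop	16108	191	7S
non-7S_a	D-loop	16026	16107	non-7S
non-7S_b	D-loop	192	578	non-7S
MT-RNR1	rRNA	650	1603	
MT-RNR2	rRNA	1673	3231	
MT-TF	tRNA	579	649	
MT-TV	tRNA	1604	1672	
MT-TL1	tRNA	3232	3306	
MT-TI	tRNA	4265	4333	
MT-TQ	tRNA	4331	4402	
MT-TM	tRNA	4404	4471	
MT-TW	tRNA	5514	5581	
MT-TA	tRNA	5589	5657	
MT-TN	tRNA	5659	5731	
MT-TC	tRNA	5763	5828	
MT-TY	tRNA	5828	5893	
MT-TS1	tRNA	7448	7516	
MT-TD	tRNA	7520	7587	
MT-TK	tRNA	8297	8366	
MT-TG	tRNA	9993	10060	
MT-TR	tRNA	10407	10471	
MT-TH	tRNA	12140	12208	
MT-TS2	tRNA	12209	12267	
MT-TL2	tRNA	12268	12338	
MT-TE	tRNA	14676	14744	
MT-TT	tRNA	15890	15955	
MT-TP	tRNA	15958	16025	
MT-ND1	mRNA	3309	4264	
MT-ND2	mRNA	4472	5513	
MT-CO1	mRNA	5906	7447	
MT-CO2	mRNA	7588	8271	
MT-ATP8	mRNA	8368	8574	
MT-ATP6	mRNA	8529	9209	
MT-CO3	mRNA	9209	9992	
MT-ND3	mRNA	10061	10406	
MT-ND4L	mRNA	10472	10768	
MT-ND4	mRNA	10762	12139	
MT-ND5	mRNA	12339	14150	
MT-ND6	mRNA	14151	14675	
MT-CYB	mRNA	14749	15889	
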