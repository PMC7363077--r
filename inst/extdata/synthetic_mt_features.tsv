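kind	name	start	end	strand
tRNA	TrnF	1	68	L
rRNA	Rnr1	69	1023	L
tRNA	TrnV	1024	1092	L
rRNA	Rnr2	1093	2673	L
tRNA	TrnL1	2674	2741	L
protein-coding	ND1	2742	3698	L
tRNA	TrnI	3699	3766	L
tRNA	TrnQ	3767	3834	H
tRNA	TrnM	3835	3902	L
protein-coding	ND2	3903	4946	L
tRNA	TrnW	4947	5014	L
tRNA	TrnA	5015	5082	H
tRNA	TrnN	5083	5150	H
noncoding	OriL	5151	5207	L
tRNA	TrnC	5208	5275	H
tRNA	TrnY	5276	5343	H
protein-coding	COX1	5344	6888	L
tRNA	TrnS1	6889	6956	H
tRNA	TrnD	6957	7024	L
protein-coding	COX2	7025	7708	L
tRNA	TrnK	7709	7776	L
protein-coding	ATP8	7777	7977	L
protein-coding	ATP6	7978	8658	L
protein-coding	COX3	8659	9390	L
tRNA	TrnG	9391	9458	L
protein-coding	ND3	9459	9803	L
tRNA	TrnR	9804	9872	L
protein-coding	ND4L	9873	10169	L
protein-coding	ND4	10170	11597	L
tRNA	TrnH	11598	11665	L
tRNA	TrnS2	11666	11733	L
tRNA	TrnL2	11734	11802	L
protein-coding	ND5	11803	13548	L
protein-coding	ND6	13549	14076	H
tRNA	TrnE	14077	14144	H
protein-coding	CYTB	14145	15287	L
tRNA	TrnT	15288	15355	L
tRNA	TrnP	15356	15423	H
D-loop	D-loop	15424	16300	L
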