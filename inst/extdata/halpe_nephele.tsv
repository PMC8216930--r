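# Annotated mitogenome architecture of Halpe nephele (15291 bp, circular, linearized at trnM).
# Coordinates 1-based inclusive on the major (J) strand; ign = intergenic nucleotides
# preceding each gene (negative = overlap); blank cells in the source table are 0.
gene	class	from	to	size	ign	strand	start_codon	stop_codon
trnM	tRNA	1	68	68		J		
trnI	tRNA	69	133	65	0	J		
trnQ	tRNA	141	209	69	7	N		
nad2	PCG	288	1301	1014	78	J	ATT	TAA
trnW	tRNA	1300	1366	67	-2	J		
trnC	tRNA	1359	1423	65	-8	N		
trnY	tRNA	1425	1490	66	1	N		
cox1	PCG	1493	3023	1531	2	J	CGA	T
trnL2	tRNA	3024	3090	67	0	J		
cox2	PCG	3091	3769	679	0	J	ATG	T
trnK	tRNA	3770	3840	71	0	J		
trnD	tRNA	3845	3914	70	4	J		
atp8	PCG	3915	4079	165	0	J	ATT	TAA
atp6	PCG	4073	4750	678	-7	J	ATG	TAA
cox3	PCG	4750	5535	786	-1	J	ATG	TAA
trnG	tRNA	5538	5604	67	2	J		
nad3	PCG	5605	5958	354	0	J	ATT	TAA
trnA	tRNA	5967	6032	66	8	J		
trnR	tRNA	6038	6103	66	5	J		
trnN	tRNA	6106	6172	67	2	J		
trnS1	tRNA	6178	6238	61	5	J		
trnE	tRNA	6253	6319	67	14	J		
trnF	tRNA	6318	6382	65	-2	N		
nad5	PCG	6383	8123	1741	0	N	ATT	T
trnH	tRNA	8124	8188	65	0	N		
nad4	PCG	8189	9527	1339	0	N	ATG	T
nad4L	PCG	9534	9818	285	6	N	ATG	TAA
trnT	tRNA	9824	9887	64	5	J		
trnP	tRNA	9888	9952	65	0	N		
nad6	PCG	9955	10485	531	2	J	ATT	TAA
cytb	PCG	10485	11636	1152	-1	J	ATG	TAA
trnS2	tRNA	11635	11698	64	-2	J		
nad1	PCG	11709	12659	951	10	N	ATA	TAG
trnL1	tRNA	12663	12730	68	3	N		
rrnL	rRNA	12706	14082	1377	-25	N		
trnV	tRNA	14083	14149	67	0	N		
rrnS	rRNA	14150	14917	768	0	N		
NCR	NCR	14918	15291	374	0	J		
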