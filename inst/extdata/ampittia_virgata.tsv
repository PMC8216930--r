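# Annotated mitogenome architecture of Ampittia virgata (15333 bp, circular, linearized at trnM).
# Coordinates 1-based inclusive on the major (J) strand; ign = intergenic nucleotides
# preceding each gene (negative = overlap); blank cells in the source table are 0.
gene	class	from	to	size	ign	strand	start_codon	stop_codon
trnM	tRNA	1	67	67		J		
trnI	tRNA	67	130	64	-1	J		
trnQ	tRNA	128	196	69	-3	N		
nad2	PCG	250	1263	1014	53	J	ATT	TAA
trnW	tRNA	1262	1328	67	-2	J		
trnC	tRNA	1321	1385	65	-8	N		
trnY	tRNA	1395	1460	66	9	N		
cox1	PCG	1471	3001	1531	10	J	CGA	T
trnL2	tRNA	3002	3068	67	0	J		
cox2	PCG	3069	3744	676	0	J	ATG	T
trnK	tRNA	3745	3815	71	0	J		
trnD	tRNA	3827	3893	67	11	J		
atp8	PCG	3894	4055	162	0	J	ATA	TAA
atp6	PCG	4049	4726	678	-7	J	ATG	TAA
cox3	PCG	4726	5511	786	-1	J	ATG	TAA
trnG	tRNA	5514	5577	64	2	J		
nad3	PCG	5578	5931	354	0	J	ATT	TAA
trnA	tRNA	5939	6005	67	7	J		
trnR	tRNA	6005	6067	63	-1	J		
trnN	tRNA	6068	6133	66	0	J		
trnS1	tRNA	6147	6207	61	13	J		
trnE	tRNA	6209	6273	65	1	J		
trnF	tRNA	6274	6341	68	0	N		
nad5	PCG	6342	8076	1735	0	N	ATT	T
trnH	tRNA	8077	8145	69	0	N		
nad4	PCG	8146	9493	1348	0	N	ATT	T
nad4L	PCG	9484	9771	288	-10	N	ATG	TAA
trnT	tRNA	9781	9845	65	9	J		
trnP	tRNA	9846	9910	65	0	N		
nad6	PCG	9913	10443	531	2	J	ATT	TAA
cytb	PCG	10446	11594	1149	2	J	ATA	TAA
trnS2	tRNA	11647	11714	68	52	J		
nad1	PCG	11733	12674	942	18	N	ATT	TAA
trnL1	tRNA	12675	12743	69	0	N		
rrnL	rRNA	12739	14120	1382	-5	N		
trnV	tRNA	14121	14185	65	0	N		
rrnS	rRNA	14185	14954	770	-1	N		
NCR	NCR	14955	15333	379	0	J		
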