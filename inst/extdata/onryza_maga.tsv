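# Annotated mitogenome architecture of Onryza maga (15381 bp, circular, linearized at trnM).
# Coordinates 1-based inclusive on the major (J) strand; ign = intergenic nucleotides
# preceding each gene (negative = overlap); blank cells in the source table are 0.
gene	class	from	to	size	ign	strand	start_codon	stop_codon
trnM	tRNA	1	68	68		J		
trnI	tRNA	99	162	64	30	J		
trnQ	tRNA	160	228	69	-3	N		
nad2	PCG	306	1319	1014	77	J	ATT	TAA
trnW	tRNA	1318	1384	67	-2	J		
trnC	tRNA	1377	1441	65	-8	N		
trnY	tRNA	1443	1507	65	1	N		
cox1	PCG	1514	3044	1531	6	J	CGA	T
trnL2	tRNA	3045	3111	67	0	J		
cox2	PCG	3112	3787	676	0	J	ATG	T
trnK	tRNA	3788	3858	71	0	J		
trnD	tRNA	3861	3929	69	2	J		
atp8	PCG	3930	4094	165	0	J	ATT	TAA
atp6	PCG	4088	4765	678	-7	J	ATG	TAA
cox3	PCG	4765	5550	786	-1	J	ATG	TAA
trnG	tRNA	5553	5618	66	2	J		
nad3	PCG	5619	5972	354	0	J	ATT	TAA
trnA	tRNA	5976	6043	68	3	J		
trnR	tRNA	6051	6115	65	7	J		
trnN	tRNA	6118	6182	65	2	J		
trnS1	tRNA	6186	6246	61	3	J		
trnE	tRNA	6249	6317	69	2	J		
trnF	tRNA	6319	6383	65	1	N		
nad5	PCG	6384	8127	1744	0	N	ATT	T
trnH	tRNA	8128	8192	65	0	N		
nad4	PCG	8193	9531	1339	0	N	ATG	T
nad4L	PCG	9536	9820	285	4	N	ATG	TAA
trnT	tRNA	9826	9890	65	5	J		
trnP	tRNA	9891	9955	65	0	N		
nad6	PCG	9958	10488	531	2	J	ATT	TAA
cytb	PCG	10491	11639	1149	2	J	ATA	TAA
trnS2	tRNA	11641	11705	65	1	J		
nad1	PCG	11728	12666	939	22	N	ATG	TAA
trnL1	tRNA	12667	12734	68	0	N		
rrnL	rRNA	12794	14175	1382	59	N		
trnV	tRNA	14176	14240	65	0	N		
rrnS	rRNA	14241	15012	772	0	N		
NCR	NCR	15013	15381	369	0	J		
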