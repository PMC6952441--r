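# taxon: Lyrognathus_crotalus
# accession: MN072398
# genome_length: 13866
# circular: TRUE
# Transcribed annotation table of the L. crotalus mitogenome (accession
# MN072398). Coordinates are 1-based inclusive on the majority strand.
# IGN arithmetic of the published table was verified row-by-row against
# these coordinates. trnI is recorded on the minority strand following
# the accompanying text. The published total genome length is reported
# as 13,865 bp in one place and 13,866 bp in another; 13,866 is used.
gene	strand	start	stop	size	anticodon	start_codon	stop_codon
trnH	-	172	220	49	GTG
nad4	-	204	1511	1308		TTG	TAA
nad4L	-	1504	1773	270		ATT
trnP	-	1762	1816	55	TGG
nad6	+	1825	2271	447		ATT	TAA
cytb	+	2271	3410	1140		ATG	TAA
trnS2	+	3376	3429	54	TGA
trnT	+	3427	3492	66	TGT
nad1	-	3466	4374	909		ATA	TAA
trnL1	-	4376	4432	57	TAG
rrnL	-	4392	5519	1128
trnV	-	5486	5547	62	TAC
rrnS	-	5543	6169	627
trnI	-	6217	6262	46	AAT
trnQ	-	6245	6343	99	TTG
CR	+	6344	6708	365
trnM	+	6709	6777	69	CAT
nad2	+	6758	7690	933		ATT	TAG
trnW	+	7689	7758	70	TCA
trnY	-	7726	7806	81	GTA
trnC	-	7772	7824	53	GCA
cox1	+	7797	9353	1557		ATA	TAG
cox2	+	9402	10019	618		ATG	TAG
trnK	+	10017	10078	62	CTT
trnD	+	10046	10121	76	GTC
atp8	+	10107	10259	153		ATT	TAA
atp6	+	10253	10921	669		ATG	TAG
cox3	+	10923	11708	786		TTG	TAA
trnG	+	11720	11764	45	GGA
nad3	+	11760	12110	351		ATT	TAA
trnL2	-	12089	12142	54	TAA
trnN	+	12137	12215	79	GTT
trnA	+	12168	12231	64
trnS1	+	12209	12269	61	GCT
trnR	+	12266	12334	69	CGA
trnE	+	12309	12370	62	TTC
trnF	-	12332	12400	69	GAA
nad5	-	12400	13845	1446		ATT	TAA
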