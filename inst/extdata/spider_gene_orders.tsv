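# 17-taxon spider gene-order panel plus the ancestral arthropod
# (Limulus polyphemus) outgroup. Orders are signed token lists on the
# majority strand, canonical rotation (cox1 first), control region (CR)
# carried as a 38th locus; "-" marks the minority strand.
#
# PROVENANCE: the Lyrognathus_crotalus row is derived from the published
# annotation table (accession MN072398). The Limulus row is the standard
# ancestral arthropod arrangement. All other rows are RECONSTRUCTED from
# the published narrative description of the panel (identical-order
# groups, per-branch rearrangements on the reference topology,
# plesiomorphic-block retention); the original supplementary listing was
# not available, so per-taxon details not fixed by that narrative
# (notably the destinations of the family-private relocations in
# Agelenidae, Dictynidae and Salticidae) are reconstruction choices and
# boundary tallies computed from them are approximate at the
# family-private level. See the provenance column.
taxon	family	group	provenance	order
Limulus_polyphemus	Xiphosura	ancestor	standard ancestral arthropod arrangement	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cytb trnS2 -nad1 -trnL1 -trnL2 -rrnL -trnV -rrnS CR trnI -trnQ trnM nad2 trnW -trnC -trnY
Liphistius_erawan	Liphistiidae	mesothelae	reconstructed: ancestral-like arrangement assumed	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cytb trnS2 -nad1 -trnL1 -trnL2 -rrnL -trnV -rrnS CR trnI -trnQ trnM nad2 trnW -trnC -trnY
Lyrognathus_crotalus	Theraphosidae	mygalomorph-A	from published annotation table (MN072398)	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Hypochilus_thorelli	Hypochilidae	mygalomorph-A	reconstructed: identical to L. crotalus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Pholcus_phalangioides	Pholcidae	mygalomorph-A	reconstructed: identical to H. thorelli per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Ornithoctonus_huwena	Theraphosidae	mygalomorph-B	reconstructed: L. crotalus arrangement with trnI on majority strand	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Calisoga_longitarsis	Nemesiidae	mygalomorph-B	reconstructed: identical to O. huwena per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Phyxioschema_suthepium	Dipluridae	mygalomorph-B	reconstructed: identical to O. huwena per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ CR trnM nad2 trnW -trnY -trnC
Oxyopes_sertatus	Oxyopidae	araneomorph-core	reconstructed: core araneomorph arrangement (trnI between nad6 and cytb)	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Wadicosa_fidelis	Lycosidae	araneomorph-core	reconstructed: identical to O. sertatus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Oxytate_striatipes	Thomisidae	araneomorph-core	reconstructed: identical to O. sertatus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Tetragnatha_maxillosa	Tetragnathidae	araneomorph-core	reconstructed: identical to O. sertatus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Araneus_angulatus	Araneidae	araneomorph-core	reconstructed: identical to O. sertatus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Neoscona_theisi	Araneidae	araneomorph-core	reconstructed: identical to O. sertatus per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Selenops_bursarius	Selenopidae	araneomorph-selenopid	reconstructed: core arrangement with trnL2 and trnC inverted per narrative	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnL2 trnN trnA trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY trnC
Carrhotus_xanthogramma	Salticidae	araneomorph-salticid	reconstructed: core arrangement with trnE and trnW relocated per narrative (destinations are reconstruction choices)	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnN trnA trnS1 trnR -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM trnE nad2 -trnY trnW -trnC
Agelena_silvatica	Agelenidae	araneomorph-agelenid	reconstructed: core arrangement with trnN inverted, (trnL2 trnN trnA) block relocated, trnI inverted per narrative (short-range destination is a reconstruction choice)	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnS1 trnR trnE -trnL2 -trnN trnA -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 -trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
Argyroneta_aquatica	Dictynidae	araneomorph-dictynid	reconstructed: core arrangement with trnN inverted then relocated between trnA and trnS1 per narrative (short-range destination is a reconstruction choice)	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 -trnL2 trnA trnN trnS1 trnR trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 trnI cytb trnS2 trnT -nad1 -trnL1 -rrnL -trnV -rrnS -trnQ CR trnM nad2 trnW -trnY -trnC
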