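(Limulus_polyphemus,(Liphistius_erawan,((((Lyrognathus_crotalus,Ornithoctonus_huwena),(Calisoga_longitarsis,Phyxioschema_suthepium)),(Hypochilus_thorelli,Pholcus_phalangioides)),((Argyroneta_aquatica,Agelena_silvatica),((Selenops_bursarius,Carrhotus_xanthogramma),(Oxytate_striatipes,(Wadicosa_fidelis,(Oxyopes_sertatus,(Tetragnatha_maxillosa,(Araneus_angulatus,Neoscona_theisi))))))))));
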