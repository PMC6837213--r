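(Taxidea_taxus,(Mellivora_capensis,((Meles_meles,Arctonyx_collaris),(Melogale_moschata,((Eira_barbara,(Gulo_gulo,(Pekania_pennanti,(Martes_flavigula,(Martes_americana,(Martes_zibellina,(Martes_martes,Martes_foina))))))),((Galictis_vittata,(Vormela_peregusna,(Ictonyx_libyca,Ictonyx_striatus))),((Lutra_lutra,(Lutrogale_perspicillata,(Amblonyx_cinereus,(Lontra_longicaudis,Enhydra_lutris)))),(Mustela_erminea,((Mustela_eversmanii,(Mustela_putorius,Mustela_lutreola)),(Mustela_sibirica,(Mustela_itatsi,Mustela_kathiah)))))))))));
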