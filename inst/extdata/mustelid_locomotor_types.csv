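species,habit
Amblonyx_cinereus,natatorial
Arctonyx_collaris,fossorial
Eira_barbara,scansorial
Enhydra_lutris,natatorial
Galictis_vittata,generalized
Gulo_gulo,generalized
Ictonyx_libyca,fossorial
Ictonyx_striatus,fossorial
Lontra_longicaudis,natatorial
Lutra_lutra,natatorial
Lutrogale_perspicillata,natatorial
Martes_americana,scansorial
Martes_flavigula,scansorial
Martes_foina,scansorial
Martes_martes,scansorial
Martes_zibellina,scansorial
Meles_meles,fossorial
Mellivora_capensis,fossorial
Melogale_moschata,fossorial
Mustela_erminea,generalized
Mustela_eversmanii,generalized
Mustela_itatsi,generalized
Mustela_kathiah,generalized
Mustela_lutreola,natatorial
Mustela_putorius,generalized
Mustela_sibirica,generalized
Pekania_pennanti,scansorial
Taxidea_taxus,fossorial
Vormela_peregusna,generalized
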