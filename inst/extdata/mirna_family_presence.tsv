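species	miR156	miR396	miR166	miR171	miR160	miR167	miR164	miR172	miR319	miR159	miR169	miR408	miR390	miR395	miR398	miR168	miR399	miR162	miR393	miR394	miR482	miR403	miR530	miR2111	miR477	miR535	miR2118
Brachypodium distachyon	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	0	0	0	1
Glycine max	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1
Arabidopsis thaliana	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	0	1	0	0	0
Oryza sativa	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	0	0	1	1
Arabidopsis lyrata	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	0	1	0	0	0
Malus domestica	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1
Prunus persica	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0
Vitis vinifera	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	0
Populus trichocarpa	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0
Solanum tuberosum	1	1	1	1	1	1	1	1	1	0	1	1	1	1	1	0	1	1	1	0	1	0	1	0	1	0	0
Citrus sinensis	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1	1	1	1	0	1	1	0
Cucumis melo	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	1	1	0	0
Manihot esculenta	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1	1	1	1	1	1	1	1	0
Amborella trichopoda	1	1	1	1	1	1	1	1	1	1	1	0	1	1	1	1	0	0	1	1	0	0	0	1	1	1	0
Medicago truncatula	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	0	1	1	0	0	1
Nicotiana tabacum	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1	1	0	0	0	1	0	0
Aegilops tauschii	1	1	1	1	1	1	1	1	1	0	1	1	1	1	1	1	1	0	1	1	0	0	0	0	0	0	1
Zea mays	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	1
Sorghum bicolor	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	1
Theobroma cacao	1	1	1	1	1	1	1	1	1	0	1	0	1	1	1	1	1	1	1	1	0	1	1	1	0	1	0
Carica papaya	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	1	1	0	0	0	0	1	1	0
Linum usitatissimum	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	0	0	0	0
Ricinus communis	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	0	0	0	1	0
Solanum lycopersicum	1	1	1	1	1	1	1	1	1	1	1	0	1	1	0	1	1	1	0	1	1	1	0	0	1	0	0
Triticum aestivum	1	1	0	1	1	1	1	0	1	1	1	1	0	1	1	0	1	0	0	0	0	0	1	0	0	0	0
Aquilegia caerulea	1	1	1	1	1	1	0	1	1	1	1	1	0	1	1	1	1	0	0	0	1	0	1	0	1	1	0
Brassica napus	1	1	1	1	1	1	1	1	0	1	1	0	1	1	0	1	1	1	1	1	0	1	0	1	0	0	0
Brassica rapa	1	1	0	1	1	1	1	1	1	1	0	1	1	1	1	1	0	1	0	0	0	1	0	1	0	0	0
Cynara cardunculus	1	1	0	1	1	1	1	1	1	0	1	1	1	1	1	1	1	0	1	1	0	0	0	0	0	0	0
Physcomitrella patens	1	0	1	1	1	1	0	0	1	0	0	1	1	1	0	0	0	0	0	0	0	0	0	0	1	1	0
Gossypium hirsutum	1	1	1	0	1	1	1	1	0	0	1	0	1	0	1	0	1	1	1	1	1	0	0	0	0	0	0
Hevea brasiliensis	1	1	1	0	0	0	0	0	1	1	0	1	0	0	1	0	0	0	0	0	1	0	0	0	0	0	1
Vigna unguiculata	1	0	0	0	1	0	1	1	1	0	1	1	0	1	0	1	1	1	0	0	1	0	0	0	0	0	1
Gossypium raimondii	0	0	1	0	0	1	1	1	0	0	0	0	0	0	1	0	1	0	0	0	1	0	1	0	1	0	0
Salvia sclarea	1	1	1	1	0	0	1	1	0	0	1	0	0	1	1	0	1	0	0	1	0	0	0	0	0	0	0
Pinus taeda	1	1	1	1	0	0	0	0	1	1	0	1	1	0	1	0	0	0	0	0	1	0	0	0	0	0	0
Festuca arundinacea	1	1	1	1	1	0	1	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Saccharum sp.	1	1	1	0	0	1	0	0	0	1	1	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
Arachis hypogaea	1	0	0	0	1	1	0	0	0	1	0	1	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0
Helianthus tuberosus	1	0	0	1	1	0	0	0	0	1	0	0	0	0	0	0	0	1	1	0	0	1	1	0	0	0	0
Hordeum vulgare	1	0	1	1	0	0	0	0	0	1	1	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0
Lotus japonicus	0	1	0	1	0	1	0	1	0	0	0	1	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0
Pinus densata	0	1	1	1	0	0	0	0	0	1	1	0	1	0	0	0	0	1	0	0	1	0	0	0	0	0	0
Selaginella moellendorffii	1	1	1	1	1	0	0	0	1	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Digitalis purpurea	1	1	1	0	1	1	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Picea abies	0	1	1	0	1	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	1	0
Acacia auriculiformis	0	1	0	0	1	0	0	1	1	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0	0	0	0
Citrus trifoliata	1	0	1	1	0	1	1	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Phaseolus vulgaris	0	0	1	0	0	0	0	0	1	1	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	1
Saccharum officinarum	1	1	0	0	0	1	0	0	0	1	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
Brassica oleracea	0	0	0	1	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0
Citrus clementina	0	1	0	1	0	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
Citrus reticulata	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0
Cunninghamia lanceolata	0	0	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
Glycine soja	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
Helianthus annuus	1	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Helianthus paradoxus	1	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Helianthus petiolaris	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0
Rehmannia glutinosa	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Acacia mangium	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Avicennia marina	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Bruguiera cylindrica	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Bruguiera gymnorhiza	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Helianthus argophyllus	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0
Helianthus ciliaris	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Panax ginseng	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	1
Chlamydomonas reinhardtii	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Elaeis guineensis	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Gossypium herbaceum	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Helianthus exilis	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Populus euphratica	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Triticum turgidum	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
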