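name,country,origin_class,allele1,allele2,flags,presumed_homozygous,phenotype,source
Big Red,,unknown,S1,Sc,a,FALSE,,this_study
Dama Rosa,,unknown,S1,Sc,a,FALSE,,this_study
Flavorcot,,unknown,S1,Sc,a,FALSE,,this_study
Rojo Pasión,,unknown,S1,Sc,a,FALSE,,this_study
Rubissia,,unknown,S1,Sc,a,FALSE,,this_study
Water,,unknown,S1,Sc,a;c,FALSE,SC,this_study
Mauricio,,unknown,S1,Sc,,FALSE,,previous
Bergecot,,unknown,S2,Sc,d,FALSE,,this_study
Canino,,unknown,S2,Sc,d,FALSE,,this_study
Harval,,unknown,S2,Sc,a,FALSE,,this_study
Justo Cot,,unknown,S2,Sc,a,FALSE,,this_study
Paviot,,unknown,S2,Sc,d,FALSE,,this_study
Primidi,,unknown,S2,Sc,d,FALSE,,this_study
Tilton,,unknown,S2,Sc,,FALSE,,this_study
Berdejo,,unknown,S2,Sc,,FALSE,,previous
Bergeron,,unknown,S2,Sc,,FALSE,,previous
Budapest,,unknown,S2,Sc,,FALSE,,previous
Dulcinea,,unknown,S2,Sc,,FALSE,,previous
Galta Vermella Valenciana,,unknown,S2,Sc,,FALSE,,previous
Kalao,,unknown,S2,Sc,,FALSE,,previous
Konservnyi Pozdnii,,unknown,S2,Sc,,FALSE,,previous
Mamaia,,unknown,S2,Sc,,FALSE,,previous
Mandulakajszi,,unknown,S2,Sc,,FALSE,,previous
Mediva,,unknown,S2,Sc,,FALSE,,previous
Peñaflor 02,,unknown,S2,Sc,,FALSE,,previous
Pepito del Rubio,,unknown,S2,Sc,,FALSE,,previous
Rakovszky,,unknown,S2,Sc,,FALSE,,previous
Regibus,,unknown,S2,Sc,,FALSE,,previous
Roxana,,unknown,S2,Sc,,FALSE,,previous
Rózsakajszi,,unknown,S2,Sc,,FALSE,,previous
Sandy cot,,unknown,S2,Sc,,FALSE,,previous
Trevatt,,unknown,S2,Sc,,FALSE,,previous
Rubista,,unknown,S3,Sc,d,FALSE,,this_study
Pricia,,unknown,S3,Sc,,FALSE,,previous
Rambo,,unknown,S3,Sc,,FALSE,,previous
Búlida,Spain,traditional,S5,Sc,,FALSE,,this_study
Fartoly,,unknown,S6,Sc,b;d,FALSE,,this_study
Ladycot,,unknown,S6,Sc,b;d,FALSE,,this_study
Medflo,,unknown,S6,Sc,d,FALSE,,this_study
Mediabel,,unknown,S6,Sc,d,FALSE,,this_study
Aprix20,,unknown,S6,Sc,,FALSE,,previous
Aprix9,,unknown,S6,Sc,,FALSE,,previous
Bebecou,,unknown,S6,Sc,,FALSE,,previous
Faralia,,unknown,S6,Sc,,FALSE,,previous
Farlis,,unknown,S6,Sc,,FALSE,,previous
Lito,,unknown,S6,Sc,,FALSE,,previous
Charisma,,unknown,S7,Sc,d,FALSE,,this_study
Ninfa,,unknown,S7,Sc,,FALSE,,this_study
Beliana,,unknown,S7,Sc,,FALSE,,previous
Sayeb,,unknown,S7,Sc,,FALSE,,previous
Gönci Magyarkajszi,,unknown,S8,Sc,,FALSE,,this_study
Luizet,,unknown,S8,Sc,b;d,FALSE,,this_study
Andornaktályai magyarkajszi,,unknown,S8,Sc,,FALSE,,previous
Cacansko zlato,,unknown,S8,Sc,,FALSE,,previous
Callatis,,unknown,S8,Sc,,FALSE,,previous
Crvena ungarska,,unknown,S8,Sc,,FALSE,,previous
Darunec malahoyeva,,unknown,S8,Sc,,FALSE,,previous
Effect,,unknown,S8,Sc,,FALSE,,previous
Kâsna ungarska,,unknown,S8,Sc,,FALSE,,previous
Krimskyi Amur,,unknown,S8,Sc,,FALSE,,previous
Nagygyümölcsû magyarkajszi,,unknown,S8,Sc,,FALSE,,previous
Nikitskyi,,unknown,S8,Sc,,FALSE,,previous
Paksi magyarkajszi,,unknown,S8,Sc,,FALSE,,previous
Pisana,,unknown,S8,Sc,,FALSE,,previous
Venus,,unknown,S8,Sc,,FALSE,,previous
Alba,,unknown,S9,Sc,a,FALSE,,this_study
Aprisweet (ASF0409),,unknown,S9,Sc,a,FALSE,,this_study
Micaelo,,unknown,S9,Sc,a,FALSE,,this_study
Tadeo,,unknown,S9,Sc,b,FALSE,,this_study
AC2,,unknown,S9,Sc,,FALSE,,previous
Ceglédi arany,,unknown,S9,Sc,,FALSE,,previous
Ceglédi bíborkajski,,unknown,S9,Sc,,FALSE,,previous
Flopria,,unknown,S9,Sc,,FALSE,,previous
Lido,,unknown,S9,Sc,,FALSE,,previous
Tom Cot,,unknown,S9,Sc,,FALSE,,previous
Modesto,,unknown,S13,Sc,,FALSE,,previous
Mari de Cenad,Romania,traditional,S19,Sc,,FALSE,,previous
Cristalí,,unknown,S20,Sc,,FALSE,,previous
Gavatxet,,unknown,S20,Sc,,FALSE,,previous
Ezzine,Tunisia,breeding,S24,Sc,,FALSE,,previous
Ananasnyi ciurpinskii,,unknown,Sc,Sc,,FALSE,,previous
Asli,,unknown,Sc,Sc,,FALSE,,previous
Borsi-féle kései rózsa,,unknown,Sc,Sc,,FALSE,,previous
Ceglédi kedves,,unknown,Sc,Sc,,FALSE,,previous
Currot,,unknown,Sc,Sc,,FALSE,,previous
GaltaRoja,,unknown,Sc,Sc,,FALSE,,previous
Gandía,,unknown,Sc,Sc,,FALSE,,previous
Ginesta,,unknown,Sc,Sc,,FALSE,,previous
Grandir,,unknown,Sc,Sc,,FALSE,,previous
Manrí,,unknown,Sc,Sc,,FALSE,,previous
NJA-8,,unknown,Sc,Sc,,FALSE,,previous
Nyujtó Ferenc emléke,,unknown,Sc,Sc,,FALSE,,previous
Palabras,,unknown,Sc,Sc,,FALSE,,previous
Palau,,unknown,Sc,Sc,,FALSE,,previous
Pannónia,,unknown,Sc,Sc,,FALSE,,previous
Pasinok,,unknown,Sc,Sc,,FALSE,,previous
Patterson,,unknown,Sc,Sc,,FALSE,,previous
Raki,,unknown,Sc,Sc,,FALSE,,previous
Rojo Carlet,,unknown,Sc,Sc,,FALSE,,previous
Sirena,,unknown,Sc,Sc,,FALSE,,previous
Sulmona,,unknown,Sc,Sc,,FALSE,,previous
Tirynthos,,unknown,Sc,Sc,,FALSE,,previous
Xirivello,,unknown,Sc,Sc,,FALSE,,previous
Zaposdolye,,unknown,Sc,Sc,,FALSE,,previous
Aprix 116,,unknown,Sc,,a,TRUE,,this_study
Cebas Red,,unknown,Sc,,,TRUE,,this_study
Cocot,,unknown,Sc,,a,TRUE,,this_study
Corbato,Spain,traditional,Sc,,d,TRUE,,this_study
Delice cot,,unknown,Sc,,d,TRUE,,this_study
Fantasme,,unknown,Sc,,a,TRUE,,this_study
Farhial,,unknown,Sc,,d,TRUE,,this_study
IPS21512,,unknown,Sc,,a,TRUE,,this_study
IPS2712,,unknown,Sc,,a,TRUE,,this_study
Laguna,,unknown,Sc,,a,TRUE,,this_study
Merino,,unknown,Sc,,a,TRUE,,this_study
Mirlo anaranjado,,unknown,Sc,,d,TRUE,,this_study
Mirlo blanco,,unknown,Sc,,d,TRUE,,this_study
Mirlo Rojo,,unknown,Sc,,,TRUE,,this_study
Mitger,,unknown,Sc,,d,TRUE,,this_study
Orange rubis,,unknown,Sc,,a,TRUE,,this_study
Precoz de Tirynthos,,unknown,Sc,,a,TRUE,,this_study
Primorosa,,unknown,Sc,,,TRUE,,this_study
Soledane,,unknown,Sc,,d,TRUE,,this_study
Tardorange,,unknown,Sc,,a,TRUE,,this_study
Valorange,,unknown,Sc,,a,TRUE,,this_study
Aprix 33,,unknown,Sc,,,TRUE,,previous
ASF0404 (Apriqueen),,unknown,Sc,,,TRUE,,previous
Dorada,,unknown,Sc,,,TRUE,,previous
Faclo,,unknown,Sc,,,TRUE,,previous
Farbaly,,unknown,Sc,,,TRUE,,previous
Farbela,,unknown,Sc,,,TRUE,,previous
Fardao,,unknown,Sc,,,TRUE,,previous
Farfia,,unknown,Sc,,,TRUE,,previous
Farius,,unknown,Sc,,,TRUE,,previous
IBCOT 13-12,,unknown,Sc,,,TRUE,,previous
IPS16121,,unknown,Sc,,,TRUE,,previous
Kioto,,unknown,Sc,,,TRUE,,previous
Memphis,,unknown,Sc,,,TRUE,,previous
Milord,,unknown,Sc,,,TRUE,,previous
Murciana,,unknown,Sc,,,TRUE,,previous
Oscar,,unknown,Sc,,,TRUE,,previous
Playa cot,,unknown,Sc,,,TRUE,,previous
Rouge cot,,unknown,Sc,,,TRUE,,previous
Rubely,,unknown,Sc,,,TRUE,,previous
Sherpa,,unknown,Sc,,,TRUE,,previous
Swired,,unknown,Sc,,,TRUE,,previous
Katy,,unknown,S1,S2,,FALSE,SC,this_study
Lorna,,unknown,S1,S2,,FALSE,SC,previous
Palsteyn,,unknown,S1,S2,,FALSE,SC,previous
Victor 1,,unknown,S2,S9,,FALSE,SC,previous
IPS20390,,unknown,S1,,,FALSE,SC,previous
Rubilis,,unknown,S1,,,FALSE,SC,previous
Golden Sweet,,unknown,S3,,,FALSE,SC,previous
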