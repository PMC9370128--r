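name,country,origin_class,allele1,allele2,flags,presumed_homozygous,phenotype,source
AC1,,unknown,S1,S2,,FALSE,,previous
Castleton,,unknown,S1,S2,,FALSE,,previous
Farmingdale,,unknown,S1,S2,,FALSE,,previous
Giovanniello,,unknown,S1,S2,,FALSE,,previous
Goldrich,,unknown,S1,S2,,FALSE,,previous
Hargrand,,unknown,S1,S2,,FALSE,,previous
Lambertin-1,,unknown,S1,S2,,FALSE,,previous
Ceglédi óriás,,unknown,S8,S9,,FALSE,,previous
Cologlu,,unknown,S8,S9,,FALSE,,previous
Ligeti óriás,,unknown,S8,S9,,FALSE,,previous
Perlecot,,unknown,S8,S9,,FALSE,,previous
Pinkcot,,unknown,S8,S9,,FALSE,,previous
Szegedi M.,,unknown,S8,S9,,FALSE,,previous
Muñoz,,unknown,S2,S6,b,FALSE,,this_study
Pandora,,unknown,S2,S6,b,FALSE,,this_study
ASF0401,,unknown,S2,S6,,FALSE,,previous
Avirine (Bergarouge),,unknown,S2,S6,,FALSE,,previous
Moniqui,,unknown,S2,S6,,FALSE,,previous
Ouardi,,unknown,S2,S7,,FALSE,,previous
Priana,,unknown,S2,S7,,FALSE,,previous
Sweet Cot,,unknown,S2,S8,d,FALSE,,this_study
Alyanak,,unknown,S2,S8,,FALSE,,previous
Holly Cot,,unknown,S2,S8,,FALSE,,previous
Apribang (ASF0405),,unknown,S6,S9,a,FALSE,,this_study
ASF0402,,unknown,S6,S9,,FALSE,,previous
Cataloglu,,unknown,S6,S9,,FALSE,,previous
Cheyenne,,unknown,S6,S9,,FALSE,,previous
Feria Cot,,unknown,S6,S9,,FALSE,,previous
Flashcot,,unknown,S6,S9,,FALSE,,previous
JNP,,unknown,S6,S9,,FALSE,,previous
Ninja,,unknown,S6,S9,,FALSE,,previous
Orangered,,unknown,S6,S9,,FALSE,,previous
Soganci,,unknown,S6,S9,,FALSE,,previous
Stark Early Orange,,unknown,S6,S9,,FALSE,,previous
Sunny Cot,,unknown,S6,S9,,FALSE,,previous
Wonder Cot,,unknown,S6,S9,,FALSE,,previous
Bedri Ahmar,Tunisia,traditional,S7,S12,,FALSE,,previous
Oud Rhayem,Tunisia,traditional,S7,S12,,FALSE,,previous
Haci Haliloglu,,unknown,S9,S13,,FALSE,,previous
Kabaasi,,unknown,S9,S13,,FALSE,,previous
Voski,Hungary,unknown,S11,S13,,FALSE,,previous
Levent,,unknown,S6,S19,,FALSE,,previous
Oueld El Oud,,unknown,S7,S8,,FALSE,,previous
Bouk Ahmed,,unknown,S7,S11,,FALSE,,previous
Hamidi,,unknown,S7,S11,,FALSE,,previous
Adedi Ahmar,,unknown,S8,S12,,FALSE,,previous
IPS23214,,unknown,S1,S3,a,FALSE,,this_study
Monred,,unknown,S1,S3,a,FALSE,,this_study
Cooper Cot,,unknown,S1,S3,,FALSE,,previous
Perfection,The USA,traditional,S1,S3,,FALSE,,previous
Mayacot,,unknown,S2,S3,,FALSE,,previous
Sun Glo,The USA,traditional,S2,S3,,FALSE,,previous
Goldstrike 02,,unknown,S2,S9,,FALSE,,previous
Hasanbey,,unknown,S2,S9,,FALSE,,previous
Magic Cot,,unknown,S2,S9,,FALSE,,previous
Samourai,,unknown,S3,S8,a;c,FALSE,SI,this_study
Lilly Cot,,unknown,S3,S8,,FALSE,,previous
Spring Blush,,unknown,S3,S8,,FALSE,,previous
Almadulce,,unknown,S3,S9,,FALSE,,previous
Flodea,,unknown,S3,S9,,FALSE,,previous
Henderson,,unknown,S3,S9,,FALSE,,previous
Kosmos,,unknown,S3,S9,,FALSE,,previous
Tsunami,,unknown,S3,S9,,FALSE,,previous
Goldbar,,unknown,S7,S9,,FALSE,,previous
Kurukabuk,,unknown,S7,S9,,FALSE,,previous
Primaya,,unknown,S1,S6,,FALSE,,previous
Farely,,unknown,S1,S9,b,FALSE,,this_study
Megatea,,unknown,S1,S9,b,FALSE,,this_study
Monster Cot,,unknown,S1,S9,b,FALSE,,this_study
Priabel,,unknown,S1,S9,b,FALSE,,this_study
Almater,,unknown,S1,S9,,FALSE,,previous
Aurora,,unknown,S1,S9,,FALSE,,previous
Medaga,,unknown,S1,S9,,FALSE,,previous
Robada,,unknown,S6,S8,,FALSE,,previous
Harcot,Canada,breeding,S1,S4,b,FALSE,,this_study
Bouthani Ben Friha,Tunisia,traditional,S12,S13,,FALSE,,previous
Cow-1,France,breeding,S1,S31,,FALSE,,previous
Cow-2,France,breeding,S20,S31,,FALSE,,previous
Estrella,,unknown,S1,S7,,FALSE,,previous
Harlayne,,unknown,S3,S20,,FALSE,,previous
Harmat,Hungary,unknown,S10,S11,,FALSE,,previous
Korai zamatos,Hungary,unknown,S12,S13,,FALSE,,previous
Mariem,,unknown,S7,S20,,FALSE,,previous
Martinet,,unknown,S2,S2,,FALSE,,previous
Oud Hmida,Tunisia,traditional,S2,S12,,FALSE,,previous
Perla,,unknown,S2,S20,,FALSE,,previous
Portici,,unknown,S2,S20,,FALSE,,previous
Shalakh (Erevani),Armenia,traditional,S5,S11,,FALSE,,previous
Velázquez,Spain,traditional,S5,S20,,FALSE,,previous
Dama taronja,,unknown,S1,,a,FALSE,,this_study
Tornado,,unknown,S1,,a,FALSE,,this_study
Vitillo,,unknown,S1,,a,FALSE,,this_study
IBCOT 18-2,,unknown,S1,,,FALSE,,previous
Fuego,,unknown,S2,,a,FALSE,,this_study
Cyrano,,unknown,S2,,,FALSE,,previous
IBCOT 29-5,,unknown,S2,,,FALSE,,previous
Veecot,,unknown,S2,,,FALSE,,previous
Mogador,,unknown,S3,,a,FALSE,,this_study
Colorado,,unknown,S3,,,FALSE,,previous
Mikado,,unknown,S3,,,FALSE,,previous
Stella,,unknown,S6,,,FALSE,,previous
Vanilla Cot,,unknown,S8,,,FALSE,,previous
Goldstrike 01,,unknown,S9,,,FALSE,,previous
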