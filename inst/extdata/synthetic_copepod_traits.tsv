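species	order	chromosome_2n	genome_size_mb
Calanoida_sp01	Calanoida	22	3400
Calanoida_sp02	Calanoida	24	3179
Calanoida_sp03	Calanoida	20	2950
Calanoida_sp04	Calanoida	18	3600
Calanoida_sp05	Calanoida	22	2800
Calanoida_sp06	Calanoida	8	529
Calanoida_sp07	Calanoida	24	4100
Calanoida_sp08	Calanoida	16	2500
Siphonostomatoida_sp01	Siphonostomatoida	14	580
Siphonostomatoida_sp02	Siphonostomatoida	12	563
Siphonostomatoida_sp03	Siphonostomatoida	14	620
Siphonostomatoida_sp04	Siphonostomatoida	12	540
Siphonostomatoida_sp05	Siphonostomatoida	14	500
Harpacticoida_sp01	Harpacticoida	12	250
Harpacticoida_sp02	Harpacticoida	10	276
Harpacticoida_sp03	Harpacticoida	12	310
Harpacticoida_sp04	Harpacticoida	14	240
Harpacticoida_sp05	Harpacticoida	12	290
Cyclopoida_sp01	Cyclopoida	10	480
Cyclopoida_sp02	Cyclopoida	14	509
Cyclopoida_sp03	Cyclopoida	12	560
Cyclopoida_sp04	Cyclopoida	10	450
Cyclopoida_sp05	Cyclopoida	16	600
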