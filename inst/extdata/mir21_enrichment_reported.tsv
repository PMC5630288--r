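description	k	n	K	N	reported_pvalue
ribonucleoprotein complex biogenesis	138	4009	342	20949	5.21E-20
ribosome biogenesis	101	4009	224	20949	5.35E-19
ncRNA metabolic process	132	4009	372	20949	5.82E-14
rRNA processing	67	4009	147	20949	2.32E-13
RNA splicing	115	4009	316	20949	3.50E-13
ncRNA processing	103	4009	273	20949	4.53E-13
mRNA metabolic process	157	4009	482	20949	9.30E-13
regulation of mitotic cell cycle	145	4009	436	20949	1.18E-12
rRNA metabolic process	67	4009	152	20949	1.60E-12
negative regulation of intracellular signal transduction	144	4009	441	20949	6.66E-12
cell cycle phase transition	109	4009	313	20949	3.35E-11
regulation of protein stability	80	4009	206	20949	3.39E-11
ubiquitin-dependent protein catabolic process	155	4009	496	20949	4.68E-11
regulation of apoptotic signaling pathway	124	4009	373	20949	5.21E-11
mRNA processing	129	4009	395	20949	8.19E-11
intrinsic apoptotic signaling pathway	95	4009	274	20949	7.84E-10
mitotic cell cycle phase transition	100	4009	294	20949	9.35E-10
response to oxidative stress	109	4009	329	20949	9.39E-10
regulation of cell cycle phase transition	81	4009	224	20949	1.47E-09
cellular respiration	54	4009	130	20949	3.12E-09
nucleoside triphosphate metabolic process	78	4009	216	20949	3.16E-09
protein import	103	4009	312	20949	3.35E-09
ribosomal small subunit biogenesis	29	4009	52	20949	4.59E-09
positive regulation of transferase activity	146	4009	488	20949	4.63E-09
glycosyl compound metabolic process	100	4009	302	20949	4.72E-09
purine nucleoside triphosphate metabolic process	73	4009	200	20949	5.88E-09
nucleoside monophosphate metabolic process	77	4009	215	20949	6.06E-09
regulation of mitotic cell cycle phase transition	75	4009	208	20949	6.77E-09
nucleoside metabolic process	96	4009	289	20949	7.95E-09
peptidyl-lysine modification	99	4009	301	20949	8.32E-09
ossification	118	4009	377	20949	8.57E-09
RNA splicing	70	4009	191	20949	9.86E-09
mRNA splicing	70	4009	191	20949	9.86E-09
cell cycle checkpoint	63	4009	166	20949	1.14E-08
purine nucleoside metabolic process	88	4009	260	20949	1.22E-08
ribonucleoprotein complex assembly	64	4009	170	20949	1.26E-08
RNA splicing	70	4009	192	20949	1.26E-08
negative regulation of cell cycle	113	4009	360	20949	1.48E-08
ribonucleoside monophosphate metabolic process	73	4009	204	20949	1.55E-08
purine ribonucleoside monophosphate metabolic process	72	4009	201	20949	1.84E-08
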