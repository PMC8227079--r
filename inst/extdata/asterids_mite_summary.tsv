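species	n_copies	n_families	mbp	pct_assembly	pct_genome	assembly_mbp	genome_size_mbp
celery	52269	83	27.71	0.83	0.80	3332.58	3470
pepper	31405	149	12.43	0.42	0.36	2935.88	3500
coffee	25038	184	12.11	1.11	0.93	1094.45	1300
carrot	31025	428	10.34	2.45	2.19	421.54	473
fennel	17861	186	5.67	0.56	0.42	1010.97	1340
common_sunflower	114089	342	73.28	2.43	2.09	3010.05	3500
java_waterdropwort	21330	217	7.79	0.61	NA	1278.51	NA
tomato	15150	119	7.07	1.00	0.79	705.93	900
potato	20368	251	7.65	0.92	0.91	828.35	844
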