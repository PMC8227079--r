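group	n_families	n_copies	mbp	largest_family	intergenic	upstream	five_prime_utr	cds	intron	three_prime_utr	downstream	genome_size_mbp
hAT-like	144	3637	1.65	217	1506	608	77	31	918	66	431	473
Mutator-like	128	6308	2.71	542	3019	1148	52	12	1343	58	676	473
Stowaway	56	11674	2.97	1452	5605	2446	109	11	1991	89	1423	473
Tourist	81	8731	2.78	1353	3867	1803	134	19	1574	110	1224	473
Unclassified	19	675	0.23	141	335	99	5	2	188	5	41	473
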