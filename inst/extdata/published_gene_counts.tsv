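gene	compartment	analyzed_sites	n_snp	n_prnae	n_correspondence
cox1	mt	1455	57	29	26
cox3	mt	771	56	24	24
cob	mt	1062	72	19	18
psbA	pt	1029	103	3	2
psbB	pt	1500	137	30	6
psbC	pt	1359	143	26	7
psbD	pt	1074	90	8	4
psbE	pt	234	17	9	2
psbI	pt	108	16	3	0
petB	pt	657	42	23	3
petD	pt	477	25	33	7
psaA	pt	2022	153	100	17
psaB	pt	2094	194	79	12
atpA	pt	1434	143	43	9
atpB	pt	1971	197	49	12
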