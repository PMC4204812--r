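center	tr_ms	slices_n	volumes_n	subjects_n
Atlanta	2000	20	205	20
Baltimore	2500	47	123	20
Bangor	2000	34	265	20
Beijing	2000	33	225	20
Berlin	2300	34	195	20
Cambridge	3000	47	119	20
Cleveland	2800	31	127	20
Dallas	2000	36	115	20
ICBM	2000	23	128	20
Leiden	2180	38	215	20
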