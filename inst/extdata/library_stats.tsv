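library	clean_tags_total	known_mirna_n	known_tags_uniq	known_tags_total	known_ratio_pct	novel_mirna_n	novel_tags_uniq	novel_tags_total	novel_ratio_pct
sBud-1	13025496	90	2281	145547	1.12	986	1205	35371	0.27
sBud-2	13672142	87	2150	96863	0.71	780	1003	22599	0.17
sBud-3	15543919	86	2172	79234	0.51	669	876	23593	0.15
sL1-1	13217393	100	2571	237953	1.8	1000	1244	47097	0.36
sL1-2	12086276	98	3140	205017	1.7	1008	1276	36970	0.31
sL1-3	13026547	91	1967	127242	0.98	854	1066	30010	0.23
sL2-1	11146588	94	2523	151824	1.36	820	1037	26207	0.24
sL2-2	13556636	90	2518	162349	1.2	737	872	21904	0.16
sL2-3	10788646	90	2485	201288	1.87	783	1005	27762	0.26
sS1-1	10821241	73	1763	48215	0.45	508	693	11804	0.11
sS1-2	11025165	76	1753	48019	0.44	483	669	10145	0.09
sS1-3	12606617	81	1902	74064	0.59	659	852	18301	0.15
sS2-1	9125465	81	2079	114250	1.25	745	982	25010	0.27
sS2-2	11303334	90	2451	130149	1.15	847	1025	26705	0.24
sS2-3	9039947	79	2144	106664	1.18	781	945	21290	0.24
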