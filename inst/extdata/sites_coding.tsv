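gene_pos	genomic_pos	rsid	ref	ref_freq	alt	alt_freq	annotation
15	29795636	rs1630223	G	0.4967	A	0.5033	Synonymous
36	29795657	rs1630185	G	0.4967	A	0.5033	Synonymous
46	29795667	.	G	0.9991	T	0.0009	Non-synonymous
99	29795720	rs56388903	A	0.1120	G	0.8880	Intronic
126	29795747	rs6932888	G	0.7156	C	0.2844	Intronic
130	29795751	rs6932596	C	0.7161	T	0.2839	Intronic
147	29795768	rs1629329	T	0.4396	C	0.5604	Intronic
188	29795809	rs1628628	C	0.5669	T	0.4331	Intronic
201	29795822	.	A	0.9963	G	0.0037	Splice site acceptor
219	29795840	.	G	0.9967	T	0.0033	Non-synonymous
292	29795913	rs41551813	A	0.9503	T	0.0497	Non-synonymous
293	29795914	rs72558173	C	0.9986	T	0.0014	Non-synonymous
297	29795918	rs80153902	G	0.9958	A	0.0042	Synonymous
306	29795927	rs72558174	G	0.9972	A	0.0028	Synonymous
324	29795945	rs9258495	G	0.9991	T	0.0009	Synonymous
366	29795987	rs78627024	G	0.9972	A	0.0028	Synonymous
372	29795993	rs1130355	G	0.4967	A	0.5033	Synonymous
482	29796103	rs1626038	T	0.4340	C	0.5660	Intronic
485	29796106	rs17875399	G	0.9526	T	0.0474	Intronic
493	29796114	.	G	0.9991	A	0.0009	Intronic
494	29796115	rs1736927	A	0.4336	C	0.5665	Intronic
498	29796119	rs201510147	G	0.9986	A	0.0014	Intronic
505	29796126	rs3215482	A	0.4828	AC	0.5172	Intronic
507	29796128	.	C	0.9517	A	0.0483	Intronic
528	29796149	.	A	0.9967	C	0.0033	Intronic
531	29796152	rs1625907	G	0.4819	C	0.5181	Intronic
607	29796228	.	G	0.9981	A	0.0019	Intronic
613	29796234	rs375939243	CA	0.4991	C	0.5009	Intronic
624	29796245	.	T	0.9991	C	0.0009	Intronic
636	29796257	rs1625035	C	0.4493	T	0.5507	Intronic
644	29796265	rs17875401	G	0.9493	T	0.0507	Intronic
652	29796273	.	C	0.9981	T	0.0019	Intronic
685	29796306	rs1624337	G	0.4986	A	0.5014	Intronic
706	29796327	rs1130356	C	0.7621	T	0.2379	Synonymous
727	29796348	rs79303923	C	0.9981	T	0.0019	Synonymous
741	29796362	.	C	0.9991	G	0.0009	Non-synonymous
748	29796369	rs3873252	A	0.9345	T	0.0655	Synonymous
755	29796376	rs12722477	C	0.8053	A	0.1947	Non-synonymous
813	29796434	rs41557518	AC	0.9642	A	0.0358	Frame Shift
871	29796492	rs17875402	G	0.9944	A	0.0056	Synonymous
1016	29796637	rs17875403	C	0.9949	T	0.0051	Intronic
1019	29796640	rs1632942	T	0.4475	C	0.5525	Intronic
1054	29796675	rs17875404	G	0.9503	T	0.0497	Intronic
1064	29796685	rs1632941	T	0.4972	C	0.5028	Intronic
1079	29796700	rs148061958	C	0.9972	T	0.0028	Intronic
1104	29796725	rs370704534	C	0.9981	G	0.0019	Intronic
1128	29796749	rs62391965	C	0.9345	A	0.0655	Intronic
1131	29796752	.	A	0.9991	T	0.0009	Intronic
1147	29796768	rs1632940	T	0.2040	C	0.7960	Intronic
1179	29796800	rs140935623	A	0.9981	G	0.0019	Intronic
1217	29796838	rs1736923	A	0.4963	G	0.5037	Intronic
1313	29796934	rs114041958	G	0.9507	A	0.0493	Intronic
1314	29796935	rs1632939	G	0.4972	A	0.5028	Intronic
1365	29796986	rs1632938	G	0.4972	A	0.5028	Intronic
1422	29797043	rs145023077	C	0.9912	T	0.0088	Intronic
1431	29797052	rs116139267	C	0.9967	T	0.0033	Intronic
1452	29797073	rs188836562	G	0.9991	C	0.0009	Intronic
1534	29797155	rs17875405	G	0.9503	C	0.0497	Intronic
1552	29797173	rs1736920	A	0.4470	G	0.5530	Intronic
1574	29797195	.	A	0.9986	AC	0.0014	Frame Shift
1590	29797211	rs41562616	C	0.9503	T	0.0497	Synonymous
1759	29797380	rs200931762	G	0.9991	A	0.0009	Non-synonymous
1799	29797420	rs12722482	C	0.9698	T	0.0302	Non-synonymous
1800	29797421	rs76951509	G	0.9963	A	0.0037	Synonymous
1827	29797448	rs17875406	G	0.9554	A	0.0446	Synonymous
1932	29797553	rs1632937	G	0.4972	C	0.5028	Intronic
2018	29797639	rs1049033	C	0.7742	T	0.2258	Synonymous
2075	29797696	rs1130363	A	0.4470	G	0.5530	Synonymous
2161	29797782	rs1611627	T	0.5627	C	0.4373	Intronic
2278	29797899	rs1632934	T	0.4972	C	0.5028	Intronic
2312	29797933	rs1632933	C	0.4972	T	0.5028	Intronic
2330	29797951	rs1736912	A	0.4972	G	0.5028	Intronic
2408	29798029	.	T	0.9991	A	0.0009	Intronic
2412	29798033	rs17179080	G	0.9707	A	0.0293	Intronic
2418	29798039	rs1632932	G	0.4972	A	0.5028	Intronic
2462	29798083	rs114038308	C	0.9345	T	0.0655	Intronic
2519	29798140	rs915667	A	0.5084	G	0.4916	Intronic
2627	29798248	rs186170315	G	0.9991	A	0.0009	Intronic
2798	29798419	rs915670	G	0.7742	A	0.2258	Intronic
2804	29798425	rs915669	G	0.4480	T	0.5520	Intronic
2838	29798459	rs915668	C	0.4480	G	0.5520	Intronic
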