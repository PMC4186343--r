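gene_pos	G*01:01:01:01	G*01:01:01:01new	G*01:01:01:04	G*01:01:01:05	G*01:01:02:01	G*01:01:03:03	G*01:03:01:02	G*01:04:01	G*01:04:04	G*01:05N	G*01:06
15	G	G	G	G	A	A	G	A	A	A	A
36	G	G	G	G	A	A	G	A	A	A	A
99	G	G	G	A	G	G	G	G	G	G	G
126	C	C	G	G	G	G	G	G	G	G	G
130	T	T	C	C	C	C	C	C	C	C	C
147	T	T	T	T	C	C	C	C	C	C	C
188	C	C	C	C	T	C	C	T	T	T	T
292	A	A	A	A	A	A	T	A	A	A	A
372	G	G	G	G	A	A	G	A	A	A	A
482	T	T	T	T	C	C	C	C	C	C	C
485	G	G	G	G	G	G	T	G	G	G	G
494	A	A	A	A	C	C	C	C	C	C	C
505	A	A	A	A	AC	AC	A	AC	AC	AC	AC
507	C	C	C	C	C	C	A	C	C	C	C
531	G	G	G	G	C	C	G	C	C	C	C
613	CA	CA	CA	CA	C	C	CA	C	C	C	C
636	C	C	C	C	T	T	T	T	T	T	T
644	G	G	G	G	G	G	T	G	G	G	G
685	G	G	G	G	A	A	G	A	A	A	A
706	C	C	C	C	T	C	C	C	C	T	T
748	A	A	A	A	A	T	A	A	A	A	A
755	C	C	C	C	C	C	C	A	A	C	C
813	AC	AC	AC	AC	AC	AC	AC	AC	AC	A	AC
1019	T	T	T	T	C	C	C	C	C	C	C
1054	G	G	G	G	G	G	T	G	G	G	G
1064	T	T	T	T	C	C	T	C	C	C	C
1128	C	C	C	C	C	A	C	C	C	C	C
1147	C	C	T	T	C	C	T	C	C	C	C
1217	A	A	A	A	G	G	A	G	G	G	G
1313	G	G	G	G	G	G	A	G	G	G	G
1314	G	G	G	G	A	A	G	A	A	A	A
1365	G	G	G	G	A	A	G	A	A	A	A
1534	G	G	G	G	G	G	C	G	G	G	G
1552	A	A	A	A	G	G	G	G	G	G	G
1590	C	C	C	C	C	C	T	C	C	C	C
1799	C	C	C	C	C	C	C	C	C	C	T
1827	G	G	G	G	G	G	G	G	A	G	G
1932	G	G	G	G	C	C	G	C	C	C	C
2018	C	C	C	C	T	C	C	C	C	T	T
2075	A	A	A	A	G	G	G	G	G	G	G
2161	T	T	T	T	C	T	T	C	C	C	C
2278	T	T	T	T	C	C	T	C	C	C	C
2312	C	C	C	C	T	T	C	T	T	T	T
2330	A	A	A	A	G	G	A	G	G	G	G
2412	G	A	G	G	G	G	G	G	G	G	G
2418	G	G	G	G	A	A	G	A	A	A	A
2462	C	C	C	C	C	T	C	C	C	C	C
2519	A	A	A	A	G	G	A	G	G	G	G
2798	G	G	G	G	A	G	G	G	G	A	A
2804	G	G	G	G	T	T	T	T	T	T	T
2838	C	C	C	C	G	G	G	G	G	G	G
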