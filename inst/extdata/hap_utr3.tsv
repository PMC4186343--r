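gene_pos	UTR-1	UTR-2	UTR-3	UTR-4	UTR-7	UTR-10	UTR-5	UTR-18	UTR-6
2960	G	GATTTGTTCATGCCT	G	G	GATTTGTTCATGCCT	G	GATTTGTTCATGCCT	G	G
3003	T	T	T	C	T	T	T	T	T
3010	G	C	C	G	C	C	C	G	G
3027	C	C	C	C	A	C	C	C	C
3035	C	C	C	C	T	C	T	C	C
3142	C	G	G	C	G	G	G	C	C
3187	G	A	A	A	A	A	A	A	A
3196	C	G	C	C	C	G	C	C	C
3227	G	G	G	G	G	G	G	A	G
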