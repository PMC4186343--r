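gene_pos	genomic_pos	rsid	ref	ref_freq	alt	alt_freq	annotation
2942	29798563	.	T	0.9986	C	0.0014	UTR
2960	29798581	rs371194629	G	0.7068	GATTTGTTCATGCCT	0.2932	UTR
3001	29798608	.	C	0.9986	T	0.0014	UTR
3003	29798610	rs1707	C	0.1152	T	0.8848	UTR
3010	29798617	rs1710	G	0.4610	C	0.5390	UTR
3027	29798634	rs17179101	C	0.9359	A	0.0641	UTR
3032	29798639	rs146339774	G	0.9967	C	0.0033	UTR
3035	29798642	rs17179108	C	0.8829	T	0.1171	UTR
3052	29798659	.	C	0.9991	T	0.0009	UTR
3092	29798699	rs180827037	G	0.9986	T	0.0014	UTR
3121	29798728	rs138249160	T	0.9967	C	0.0033	UTR
3142	29798749	rs1063320	C	0.4484	G	0.5516	UTR
3177	29798784	.	G	0.9991	T	0.0009	UTR
3183	29798790	rs187320344	G	0.9991	A	0.0009	UTR
3187	29798794	rs9380142	A	0.7045	G	0.2955	UTR
3196	29798803	rs1610696	C	0.7625	G	0.2375	UTR
3227	29798834	rs1233331	G	0.9707	A	0.0293	UTR
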