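gene_pos	genomic_pos	rsid	ref	ref_freq	alt	alt_freq	alt2	alt2_freq	annotation	label
-1305	29794317	rs1736936	G	0.4995	A	0.5005	.	.	Promoter	-1305
-1179	29794443	rs1736935	A	0.4466	G	0.5534	.	.	Promoter	-1179
-1155	29794467	rs3823321	G	0.8020	A	0.1980	.	.	Promoter	-1155
-1140	29794482	rs1736934	A	0.6952	T	0.3048	.	.	Promoter	-1140
-1138	29794484	rs17875389	A	0.9493	G	0.0507	.	.	Promoter	-1138
-1121	29794501	rs3115630	T	0.0428	C	0.9572	.	.	Promoter	-1121
-1098	29794524	rs146374870	G	0.9972	A	0.0028	.	.	Promoter	-1098
-964	29794658	rs1632947	G	0.4986	A	0.5014	.	.	Promoter	-964
-922	29794700	rs370338057	C	0.9981	A	0.0019	.	.	Promoter	-922
-810	29794812	rs182801644	C	0.9986	T	0.0014	.	.	Promoter	-810
-762	29794860	rs1632946	C	0.4972	T	0.5028	.	.	Promoter	-762
-725	29794897	rs1233334	G	0.0953	C	0.8550	T	0.0497	Promoter	-725
-716	29794906	rs2249863	T	0.4963	G	0.5037	.	.	Promoter	-716
-689	29794933	rs2735022	A	0.4963	G	0.5037	.	.	Promoter	-689
-666	29794956	rs35674592	G	0.4981	T	0.5019	.	.	Promoter	-666
-646	29794976	rs17875391	A	0.9749	G	0.0251	.	.	Promoter	-646
-633	29794989	rs1632944	G	0.4995	A	0.5005	.	.	Promoter	-633
-546	29795076	rs201221694	A	0.9744	AG	0.0256	.	.	Promoter	-546/-540
-541	29795081	rs368205133	GA	0.9545	G	0.0455	.	.	Promoter	-541/-533
-539	29795083	rs112940953	A	0.9967	G	0.0033	.	.	Promoter	-539
-521	29795101	rs138987412	C	0.9986	A	0.0014	.	.	Promoter	-521
-509	29795113	rs17875393	C	0.9559	G	0.0441	.	.	Promoter	-509
-486	29795136	rs1736933	A	0.4991	C	0.5009	.	.	Promoter	-486
-483	29795139	rs149890776	A	0.9717	G	0.0283	.	.	Promoter	-483
-477	29795145	rs1736932	C	0.4461	G	0.5539	.	.	Promoter	-477
-443	29795179	rs17875394	G	0.9638	A	0.0362	.	.	Promoter	-443
-400	29795222	rs17875395	G	0.9559	A	0.0441	.	.	Promoter	-400
-391	29795231	rs17875396	G	0.9559	A	0.0441	.	.	Promoter	-391
-369	29795253	rs1632943	C	0.4480	A	0.5520	.	.	Promoter	-369
-355	29795267	rs191630481	G	0.9967	A	0.0033	.	.	Promoter	-355
-284	29795338	.	G	0.9991	A	0.0009	.	.	Promoter	-284
-256	29795366	.	TC	0.9958	T	0.0042	.	.	Promoter	-256
-201	29795421	rs1233333	G	0.4967	A	0.5033	.	.	Promoter	-201
-150	29795472	.	C	0.9977	T	0.0023	.	.	Promoter	-150
-56	29795566	rs17875397	C	0.9503	T	0.0497	.	.	Promoter	-56
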