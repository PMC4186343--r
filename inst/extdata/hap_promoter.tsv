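gene_pos	010102a	010101a	010104a	010101b	010101f	010101c	010104b	010101d	0103a	0103e
-1305	A	G	A	G	G	G	A	G	G	G
-1179	G	A	G	A	A	A	G	A	G	G
-1155	G	G	A	G	G	G	A	G	G	G
-1140	T	A	A	A	A	A	A	A	A	A
-1138	A	A	A	A	A	A	A	A	G	G
-1121	C	C	C	C	C	T	C	C	C	C
-964	A	G	A	G	G	G	A	G	G	G
-762	T	C	T	C	C	C	T	C	C	C
-725	C	C	C	G	C	G	C	C	T	T
-716	G	T	G	T	T	T	G	T	T	T
-689	G	A	G	A	A	A	G	A	A	A
-666	T	G	T	G	G	G	T	G	G	G
-646	A	A	A	A	A	A	A	A	A	G
-633	A	G	A	G	G	G	A	G	G	G
-546	A	A	A	A	A	A	A	A	AG	A
-541	GA	GA	GA	GA	G	GA	GA	GA	GA	GA
-509	C	C	C	C	C	C	C	C	G	G
-486	C	A	C	A	A	A	C	A	A	A
-483	A	A	A	A	A	A	A	G	A	A
-477	G	C	G	C	C	C	G	C	G	G
-443	G	G	G	G	G	G	A	G	G	G
-400	G	G	G	G	G	G	G	G	A	A
-391	G	G	G	G	G	G	G	G	A	A
-369	A	C	A	C	C	C	A	C	A	A
-201	A	G	A	G	G	G	A	G	G	G
-56	C	C	C	C	C	C	C	C	T	T
15	A	G	A	G	G	G	A	G	G	G
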