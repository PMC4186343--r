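name	global_freq
010102a	0.2825
010101a	0.2728
010104a	0.1501
010101b	0.0520
010101f	0.0446
010101c	0.0418
010104b	0.0353
010101d	0.0260
0103a	0.0191
0103e	0.0149
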