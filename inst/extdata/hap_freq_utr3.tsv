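name	global_freq
UTR-1	0.2904
UTR-2	0.1938
UTR-3	0.1938
UTR-4	0.1083
UTR-7	0.0558
UTR-10	0.0367
UTR-5	0.0358
UTR-18	0.0283
UTR-6	0.0125
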