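name	global_freq
G*01:01:01:01	0.2528
G*01:01:01:01new	0.0200
G*01:01:01:04	0.0376
G*01:01:01:05	0.0911
G*01:01:02:01	0.1445
G*01:01:03:03	0.0627
G*01:03:01:02	0.0446
G*01:04:01	0.1329
G*01:04:04	0.0404
G*01:05N	0.0330
G*01:06	0.0283
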