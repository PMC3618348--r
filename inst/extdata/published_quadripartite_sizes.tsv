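species	plastome_size	lsc_size	ssc_size	ir_size	pct_gene	pct_intron	pct_intergenic
Lolium perenne	135282	79972	12428	21441	54.34	11.91	33.75
Lolium multiflorum	135175	79848	12485	21421	53.56	12.01	33.49
Festuca pratensis	135291	79934	12511	21423	53.54	11.91	33.61
Festuca arundinacea	136048	80560	11300	22600	54.20	9.31	36.49
Festuca altissima	135272	79828	12598	21423	53.64	11.99	33.44
Festuca ovina	133165	78329	12386	21225	54.50	12.19	32.33
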