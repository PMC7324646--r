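rsid	gene	ref	alt	risk_genotypes	annotation
rs1042522	TP53	G	C	GG,CG	Decreased response to cisplatin, paclitaxel, capecitabine, and oxaliplatin compared with the CC genotype.
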