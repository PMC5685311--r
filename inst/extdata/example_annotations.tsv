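chrom	pos	ref	alt	gene	consequence	maf_1000g	maf_esp	maf_exac	polyphen	sift	cadd	in_hgmd	in_clinvar	hgvs_c	hgvs_p
21	27264108	G	A	APP	missense	.	.	0.00006	probably_damaging	deleterious	5.483	TRUE	TRUE	c.2137G>A	p.Ala713Thr
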