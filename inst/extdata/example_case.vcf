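##fileformat=VCFv4.2
##source=neuropanel_example
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	CASE01
21	27264108	.	G	A	.	PASS	.	GT:DP	0/1:94
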