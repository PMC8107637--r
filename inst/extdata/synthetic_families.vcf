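##fileformat=VCFv4.2
##source=founderhap-fixture
##note=synthetic stand-in positions inside the target gene; genotype-level transcription of the cohort segregation patterns
##contig=<ID=chr17>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	M1	P1	F2F	F2M	P2a	P2b	M3	P3	F4F	P4	P5	S5a	S5b	S5c	P6	M7	P7a	P7b	P8
chr17	74863210	c.461C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr17	74863900	c.577C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr17	74864120	c.614C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
chr17	74864510	c.724C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1
chr17	74864890	c.823C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr17	74864990	c.916C>T	C	T	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1
chr17	74865010	c.925C>T	C	T	.	PASS	GENE=FDXR;CSQ=stop_gain	GT	0/0	0/0	0/1	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr17	74865062	c.1115C>A	C	A	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/1	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	1/1	0/0	0/1	0/1	0/0
chr17	74865300	c.1189G>A	G	A	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/1	0/0
chr17	74865710	c.1279G>C	G	C	.	PASS	GENE=FDXR;CSQ=missense	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
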