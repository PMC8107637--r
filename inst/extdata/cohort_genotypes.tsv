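family	n_affected	allele	hgvs_p	type	domain	gnomad_af	origin
1	1	c.577C>T	p.(Arg193Cys)	missense	FAD/NAD(P) BD	0.000006573	maternal
1	1	c.1115C>A	p.(Pro372His)	missense	FAD/NAD(P) BD	0.00001315	unobserved
2	2	c.925C>T	p.(Arg309*)	stop_gain	FAD/NAD(P) BD	0.00002628	paternal
2	2	c.1115C>A	p.(Pro372His)	missense	FAD/NAD(P) BD	0.00001315	maternal
3	1	c.461C>T	p.(Ala154Val)	missense	FAD/NAD(P) BD	0	unobserved
3	1	c.823C>T	p.(Arg275Trp)	missense	FAD/NAD(P) BD	0	maternal
4	1	c.1115C>A	p.(Pro372His)	missense	FAD/NAD(P) BD	0.00001315	unobserved
4	1	c.1279G>C	p.(Ala427Pro)	missense	NAD(P) BD	0	paternal
5	1	c.614C>T	p.(Thr205Met)	missense	FAD/NAD(P) BD	0.00001314	sibling
5	1	c.823C>T	p.(Arg275Trp)	missense	FAD/NAD(P) BD	0	unobserved
6	1	c.1115C>A	p.(Pro372His)	missense	FAD/NAD(P) BD	0.00001315	unobserved
6	1	chr17:74818633-74888183del	whole_gene_deletion	deletion	Whole gene deletion	0	unobserved
7	2	c.1115C>A	p.(Pro372His)	missense	FAD/NAD(P) BD	0.00001315	unobserved
7	2	c.1189G>A	p.(Gly397Ser)	missense	NAD(P) BD	0.00003285	maternal
8	1	c.724C>T	p.(Arg242Trp)	missense	FAD/NAD(P) BD	0.000006573	unobserved
8	1	c.916C>T	p.(Arg306Cys)	missense	FAD/NAD(P) BD	0.00004600	unobserved
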