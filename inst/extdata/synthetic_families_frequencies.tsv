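chrom	pos	ref	alt	af
chr17	74863210	C	T	0
chr17	74863900	C	T	0.000006573
chr17	74864120	C	T	0.00001314
chr17	74864510	C	T	0.000006573
chr17	74864890	C	T	0
chr17	74864990	C	T	0.000046
chr17	74865010	C	T	0.00002628
chr17	74865062	C	A	0.00001315
chr17	74865300	G	A	0.00003285
chr17	74865710	G	C	0
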