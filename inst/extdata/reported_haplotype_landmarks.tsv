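landmark	chrom	pos	id
core_start	chr17	74819055	rs35292847
core_end	chr17	74947323	rs34805215
breakpoint_reference	chr17	74863955	.
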