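sample	chrom	start	end	cn	evidence
P6	chr17	74818633	74888183	1	synthetic transcription of the reported whole-gene deletion call
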