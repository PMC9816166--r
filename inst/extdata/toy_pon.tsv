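chrom	pos	ref	alt
1	900	C	T
1	1000	C	A
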