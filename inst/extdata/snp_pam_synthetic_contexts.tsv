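snp	ref	alt	position	context
SNP1	G	C	9	AAAAAGGGGATAAAAA
SNP2	C	G	8	AAAATCCCCTAAAAA
SNP3	G	A	8	AAAAATGGGGAAAAA
SNP4	C	G	6	AATTTCCAAAAAA
SNP5	G	C	8	AAAAAAAGCCAAAAA
SNP6	C	G	8	AAAAATACTGAAAAA
SNP7	C	T	8	AAAAAGTCAAAAAA
SNP8	A	G	6	AAAATATAAAA
SNP9	A	G	6	AAAATATAAAA
SNP10	T	C	11	AAAAAGTGAGTAAAAA
SNP11	A	G	7	AAAAACACCAAAAA
SNP12	A	G	9	AAAAAGGCAGGAAAAA
SNP13	G	A	7	AAAAACGGGAAAAA
SNP14	T	C	6	AAAAATAAAAA
SNP15	A	G	9	AAAAATGCATAAAA
SNP16	G	A	8	AAAAATCGAGTAAAAA
SNP17	A	G	8	AAAAAAAAAAAAAAA
SNP18	C	T	7	AAAAAGCCTAAAAA
SNP19	C	T	8	AAAAACACGCCAAAAA
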