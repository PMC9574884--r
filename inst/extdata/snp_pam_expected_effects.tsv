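snp	enzyme	effect	strand	ref_motif	alt_motif
SNP1	SpCas9	loss	positive	GG[G]	GG[C]
SNP1	SpCas9_VQR	loss	positive	GGG[G]	GGG[C]
SNP1	SpCas9_VQR	loss	positive	G[G]AT	G[C]AT
SNP1	SaCas9	loss	positive	GGG[G]AT	GGG[C]AT
SNP2	SpCas9	loss	negative	AG[G]	AG[C]
SNP2	SpCas9	loss	negative	G[G]G	G[C]G
SNP2	SpCas9_VQR	loss	negative	G[G]GG	G[C]GG
SNP3	SpCas9	loss	positive	TG[G]	TG[A]
SNP3	SpCas9_VQR	loss	positive	G[G]GG	G[A]GG
SNP3	SpCas9_EQR	gain	positive	TG[G]G	TG[A]G
SNP4	SpCas9	loss	negative	TG[G]	TG[C]
SNP5	SpCas9	gain	negative	GG[C]	GG[G]
SNP5	SpCas9	loss	positive	AA[G]	AA[C]
SNP6	SpCas9	gain	positive	TA[C]	TA[G]
SNP6	SpCas9	loss	negative	CA[G]	CA[C]
SNP6	SpCas9_VQR	gain	positive	A[C]TG	A[G]TG
SNP7	SpCas9_VQR	loss	negative	T[G]AC	T[A]AC
SNP10	SaCas9	loss	positive	GTGAG[T]	GTGAG[C]
SNP11	SpCas9_VRER	gain	negative	GG[T]G	GG[C]G
SNP12	SpCas9_VQR	gain	positive	GGC[A]	GGC[G]
SNP12	SpCas9_VRER	gain	positive	GGC[A]	GGC[G]
SNP12	SpCas9_VQR	gain	positive	C[A]GG	C[G]GG
SNP13	SpCas9_VQR	loss	positive	C[G]GG	C[A]GG
SNP15	SpCas9_VQR	gain	positive	TGC[A]	TGC[G]
SNP15	SpCas9_EQR	gain	positive	TGC[A]	TGC[G]
SNP16	SpCas9_VQR	loss	positive	C[G]AG	C[A]AG
SNP16	SpCas9_EQR	loss	positive	C[G]AG	C[A]AG
SNP16	SaCas9	loss	positive	TC[G]AGT	TC[A]AGT
SNP17	SpCas9	gain	positive	AA[A]	AA[G]
SNP17	SpCas9_VQR	gain	positive	A[A]AA	A[G]AA
SNP17	AsCpf1	loss	negative	TT[T]T	TT[C]T
SNP18	SpCas9	loss	negative	AG[G]	AG[A]
SNP18	SpCas9_VQR	gain	negative	AG[G]C	AG[A]C
SNP19	SpCas9_VQR	loss	negative	GGC[G]	GGC[A]
SNP19	SpCas9_VRER	loss	negative	GGC[G]	GGC[A]
SNP19	SpCas9_VQR	loss	negative	C[G]TG	C[A]TG
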