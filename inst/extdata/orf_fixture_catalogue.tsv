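orf_id	transcript_id	gene_id	gene_name	chrom	strand	g_min	g_max	length_nt	start_codon	category	peptide
o_ann	txA	gA	GENEA	c1	+	1000	1038	39	ATG	annotated	MKLVANNPQRST
o_int	txA	gA	GENEA	c1	+	2000	2029	30	ATG	intORF	ACDEFGHIK
o_int2	txA	gA	GENEA	c1	+	3000	3032	33	ATG	intORF	WWWTTTYYYK
o_nc1	txB	gB	GENEB	c2	+	1000	1032	33	ATG	novel_nc	MSSSLLLKDE
o_nc2	txB	gB	GENEB	c2	+	5000	5032	33	ATG	novel_nc	MTTTPPPKWW
o_nc3	txC	gC	GENEC	c2	+	8000	8032	33	ATG	novel_nc	MNNNNKLLLK
o_nc4	txC	gC	GENEC	c2	+	9000	9032	33	CTG	novel_nc	MQQQQKAAAK
o_nc5	txC	gC	GENEC	c2	+	10000	10032	33	GTG	novel_nc	MVVVVKDDDK
o_nc6	txD	gD	GENED	c2	-	11000	11032	33	ATG	novel_nc	MCCCCKEEEK
o_nc7	txD	gD	GENED	c2	-	12000	12032	33	ATG	novel_nc	MDDDDKFFFK
o_nc8	txD	gD	GENED	c2	-	13000	13032	33	TTG	novel_nc	MHHHHKRRRK
o_long	txE	gE	GENEE	c3	+	1000	1050	51	ATG	novel_nc	MAAAAKEEEEKCCCCK
o_short	txE	gE	GENEE	c3	+	1018	1050	33	ATG	novel_nc	EEEEKCCCCK
o_u1	txF	gF	GENEF	c4	+	500	541	42	ATG	uORF	MKMGGGGKHHHHK
o_u2	txF	gF	GENEF	c4	+	506	541	36	ATG	uORF	MGGGGKHHHHK
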