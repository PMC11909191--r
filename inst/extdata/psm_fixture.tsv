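spectrum_id	sample_id	peptide	orf_ids	score	is_decoy
sp01	s1	MCCCCKEEEK	o_nc6	22	FALSE
sp01	s1	MDDDDKFFFK	o_nc7	21	FALSE
sp02	s2	MSSSLLLKDE	o_nc1	23	FALSE
sp02	s2	MHHHHKRRRK	o_nc8	20	FALSE
sp03	s1	MKLVANNPQRST	o_ann	30	FALSE
sp04	s1	MKLVANNPQRST	o_ann	28	FALSE
sp05	s2	MKLVANNPQRST	o_ann	27.5	FALSE
sp06	s1	ACDEFGHIK	o_int	30	FALSE
sp07	s2	ACDEFGHIK	o_int	25	FALSE
sp08	s3	ACDEFGHIK	o_int	24.5	FALSE
sp09	s1	WWWTTTYYYK	o_int2	27	FALSE
sp10	s2	WWWTTTYYYK	o_int2	24	FALSE
sp11	s1	MSSSLLLKDE	o_nc1	29	FALSE
sp12	s2	MSSSLLLKDE	o_nc1	24.2	FALSE
sp13	s3	MSSSLLLKDE	o_nc1	23.8	FALSE
sp14	s1	MTTTPPPKWW	o_nc2	26	FALSE
sp15	s2	MTTTPPPKWW	o_nc2	23.5	FALSE
sp16	s1	MAAAAKEEEEKCCCCK	o_long	31	FALSE
sp17	s2	MAAAAKEEEEKCCCCK	o_long	26.8	FALSE
sp18	s1	EEEEKCCCCK	o_long;o_short	25.5	FALSE
sp19	s3	EEEEKCCCCK	o_long;o_short	23.2	FALSE
sp20	s1	MGGGGKHHHHK	o_u1;o_u2	26.5	FALSE
sp21	s2	MGGGGKHHHHK	o_u1;o_u2	22.5	FALSE
sp22	s1	MNNNNKLLLK	o_nc3	12	FALSE
sp23	s2	MQQQQKAAAK	o_nc4	11	FALSE
sp24	s3	MVVVVKDDDK	o_nc5	10.5	FALSE
sp25	s1	KRRDECAAAR	DECOY	13	TRUE
sp26	s2	KPPLECDDDR	DECOY	12.5	TRUE
sp27	s1	KWWMECGGGR	DECOY	11.5	TRUE
sp28	s3	KYYFECHHHR	DECOY	9	TRUE
sp29	s2	KSSVECNNNR	DECOY	8	TRUE
sp30	s1	KTTIECQQQR	DECOY	7	TRUE
sp31	s3	KVVAECSSSR	DECOY	6	TRUE
sp32	s2	KLLGECTTTR	DECOY	5	TRUE
sp33	s1	MTTTPPPKWW	o_nc2	22.8	FALSE
sp34	s3	WWWTTTYYYK	o_int2	23.9	FALSE
sp35	s3	MKLVANNPQRST	o_ann	26.2	FALSE
sp36	s3	MAAAAKEEEEKCCCCK	o_long	25.9	FALSE
sp37	s2	MGGGGKHHHHK	o_u1;o_u2	21.5	FALSE
sp38	s3	EEEEKCCCCK	o_long;o_short	22.9	FALSE
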