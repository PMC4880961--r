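mirna_id	count	seq_5p	seq_3p
PgmiR08	4807	-	TCAAGTGATGATTGACGAGATC
PgmiR09	852	AGGCCCCACTGACCGTCGGAT	-
PgmiR14	358	-	TTTGATTCGAGGAATAAAGGC
PgmiR19	245	CTGTTTGGATTGCAGGTTATG	-
PgmiR20	102	-	TTAGATGACCATCAACAAACA
PgmiR22	1615	GGAATGGTTGTCTGGCTCGAGG	-
PgmiR23	323	CAGGAAGAGCAGTGAGCACGCAA	-
PgmiR25	115	GAAGCTGACGAGGGAGAGTGG	-
PgmiR31	255	-	TACTAGCTGTAGGGATATTGC
PgmiR35	1350	AATTGGACGGAAAAGACAGGG	-
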