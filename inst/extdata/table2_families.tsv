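family	count	sequence	mirbase_ref
miR157	4015427	TTGACAGAAGATAGAGAGCAC	ath-miR157a
miR156	1632172	TGACAGAAGAGAGTGAGCAC	csi-miR156
miR166	454425	TCGGACCAGGCTTCATTCCCC	pvu-miR166a
miR168	299953	TCGCTTGGTGCAGGTCGGGAA	ath-miR168a-5p
miR167	159932	TGAAGCTGCCAGCATGATCTGA	ccl-miR167a
miR535	104111	TGACAACGAGAGAGAGCACGC	ppt-miR535a
miR169	84700	TGAGCCAAGAATGACTTGCCGG	cme-miR169t
miR390	33324	AAGCTCAGGAGGGATAGCGCC	ath-miR390a-5p
miR479	19760	CGTGATGTTGGTTCGGCTCATC	ghr-miR479
miR171	10381	CGAGCCGAATCAATATCACTC	csi-miR171b
miR2916	8924	GGGGCTCGAAGACGATCAGATA	peu-miR2916
miR482	4825	TTCCCAAGGCCGCCCATTCCGA	mdm-miR482a-3p
miR160	4710	GCGTATGAGGAGCCATGCATA	ptc-miR160b-3p
miR4414	4472	TGTGAATGATGCGGGAGATAC	mtr-miR4414b
miR159	4088	TTTGGATTGAAGGGAGCTCTA	ptc-miR159a
miR164	2755	TGGAGAAGCAGGGCACGTGCA	ptc-miR164a
miR6300	2507	GTCGTTGTAGTATAGTGGT	gma-miR6300
miR319	2113	TAGCTGCCGACTCATTCATCCA	ppe-miR319b
miR894	1830	GTTCGTTTCACGTCGGGTTCACCA	ppt-miR894
miR408	1620	CTGGGAACAGGCAGGGCATGG	ptc-miR408-5p
miR172	1608	AGAATCTTGATGATGCTGCAT	ptc-miR172a
miR162	1581	TCGATAAACCTCTGCATCCAG	ptc-miR162a
miR396	1566	GCTCAAGAAAGCTGTGGGAAA	ath-miR396b-3p
miR3639	1389	AAATGACTTCTGAACGGCAAAAC	vvi-miR3639-5p
miR6248	792	TAATTGTGGATGGAGGTAT	osa-miR6248
miR1171	721	TGGGAATGGAGTGGAGTGGAGTAG	cre-miR1171
miR858	658	TTCGTTGTCTGTTCGACCTTG	ath-miR858b
miR5653	533	TGAGAGTTGAGTTGAGTTGAGTTT	ath-miR5653
miR530	513	TGCATTTGCACCTGCACCTTA	ptc-miR530a
miR4415	511	AAGGTTGTGATTGGAATTAATGGC	gma-miR4415b-5p
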