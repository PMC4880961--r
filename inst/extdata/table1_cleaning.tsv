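read_type	count	percent
total_raw	30000000	NA
high_quality	29948480	100.00
adapter3_null	43776	0.15
insert_null	5228	0.02
adapter5_contam	92262	0.31
short_lt18	115751	0.39
polyA	1429	0.00
clean	29690034	99.14
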