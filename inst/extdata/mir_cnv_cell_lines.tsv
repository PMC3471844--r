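mirna_id	cytoband	start	end	mean_cn	expression	cell_lines
miR-7	9q21.32	85774483	85774592	0.9596	low	EOL-1, NOMO1, F36P, K562, KYO
miR-15a	13q14.2	50623255	50623337	1.071	low	F36P, K562
miR-16-1	13q14.2	50623109	50623197	1.071	low	F36P, K562
miR-192	11q13.1	64415185	64415294	3.365	high	KAS-1, OCI-AML2, F36P, HEL, K562, KU812, KYO, MEG01
miR-194	11q13.1	64415403	64415487	3.365	high	KAS-1, F36P, HEL, KG-1, K562, KU812, MEG01
miR-100	11q24.1	121528147	121528226	3.099	high	HEL, TF-1, KU812, KYO
miR-125b	11q24.1	121475675	121475762	3.099	high	HEL, TF-1, KU812, KYO, MEG01
miR-370	14q32.31	121528127	121528246	3.671	high	TF-1, KU812, K562, MEG01
miR-127	14q32.31	100419069	100419165	3.671	high	TF-1, KU812, K562, MEG01
miR-134	14q32.31	100590777	100590849	3.671	high	TF-1, KU812, MEG01
miR-154	14q32.31	100595845	100595928	3.671	high	TF-1, KU812, K562, MEG01
miR-376	14q32.31	100576872	100576939	3.671	high	KU812, MEG01
miR-379	14q32.31	100558156	100558222	3.671	high	KU812, MEG01
miR-382	14q32.31	100590396	100590471	3.671	high	TF-1, KU812, MEG01
miR-409-5p	14q32.31	100601390	100601468	3.671	high	TF-1, KU812, MEG01
miR-432	14q32.31	100420573	100590471	3.671	high	TF-1, KU812, K562, MEG01
miR-433	14q32.31	100417976	100418068	3.671	high	TF-1, KU812, K562, MEG01
miR-485-5p	14q32.31	100558156	100558222	3.671	high	TF-1, KU812, MEG01
miR-494	14q32.31	100565724	100565804	3.671	high	TF-1, KU812, MEG01
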