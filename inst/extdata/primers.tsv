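name	pool	orientation	sequence	expected_position
27f	27f_simple	forward	AGAGTTTGATCCTGGCTCAG	27
27f_v1	27f_pool	forward	AGAGTTTGATYMTGGCTCAG	27
27f_v2	27f_pool	forward	AGGGTTCGATTCTGGCTCAG	27
27f_v3	27f_pool	forward	AGAATTTGATCTTGGTTCAG	27
319f	319f	forward	ACTCCTRCGGGAGGCAGCAG	319
338r	338r	reverse	GCTGCCTCCCGTAGGAGT	338
341f	341f	forward	CCTACGGGNGGCWGCAG	341
357f	357f	forward	CCTACGGGAGGCAGCAG	357
515f	515f	forward	GTGCCAGCMGCCGCGGTAA	515
515r	515r	reverse	TTACCGCGGCKGCTGVCAC	515
534r	534r	reverse	ATTACCGCGGCTGCTGG	534
805r	805r	reverse	GACTACHVGGGTATCTAATCC	805
806r	806r	reverse	GGACTACHVGGGTWTCTAAT	806
907r	907r	reverse	CCGTCAATTCMTTTRAGT	907
926r	926r	reverse	CCGTCAATTCMTTTRAGT	926
967f	967f	forward	CAACGCGARGAACCTTACC	967
1061r	1061r	reverse	ACAACACGAGCTGACGAC	1061
515r_chl_a	515r_chl	reverse	TTACCGCGGCKGCTGVCAC	515
515r_chl_b	515r_chl	reverse	TTACCGCAGCTGCTGGCAC	515
534r_chl	534r_chl	reverse	TTACCGCRGCTGCTGGCAC	534
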