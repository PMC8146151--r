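oligo_name	direction	sequence	position
LJV_Part_1	FW	GCTCTGAAGGCCTTGGAAAC	22-41
LJV_Part_1	RV	ACGTATCGGGTTCTGTCTCC	721-702
LJV_Part_2	FW	GTGTGTGGCGTTACGATTCT	639-658
LJV_Part_2	RV	TGCGAGGTCCATCATAACATG	1334-1314
LJV_Part_3	FW	TCATACCAAATCGATACACTCCG	1260-1282
LJV_Part_3	RV	ATGTACTCAAGAGGCGTCGG	1960-1941
LJV_Part_4	FW	GAGGAACCGTGATAGCTGGG	1913-1932
LJV_Part_4	RV	ATCTTCGAGTCAGGAGCAGT	2660-2641
LJV_Part_5	FW	CCTGGAGCTGTGCAAGTTTC	2500-2519
LJV_Part_5	RV	AAAGTAACCGTGCCGCAATT	3341-3322
LJV_Part_6	FW	TTCCGATTTTGGCGTGGTTC	3223-3242
LJV_Part_6	RV	CGCCCCATGTTTGTAAGCAA	4019-4000
LJV_Part_7	FW	TCAACAGGCCTTAACATCACT	3940-3860
LJV_Part_7	RV	CTGGCGAACACCTTAAGTCG	4696-4677
LJV_Part_8	FW	CGGCGTGTTATTGATCTTCCA	4585-4560
LJV_Part_8	RV	TTCGACGTTCTTGGTTGTCA	5323-5304
LJV_Part_9	FW	TGAGTGACGAAGAGAGTTTGTC	5168-5189
LJV_Part_9	RV	TGGGACATTACAAGGACGGG	5870-5851
LJV_Part_10	FW	CCAATCAGTAGGTCCGTGGT	5802-5821
LJV_Part_10	RV	TCCGAGTCATTCTGTGCTGT	6527-6508
LJV_Part_11	FW	GCACGTATTCCACCTACAGC	6493-6512
LJV_Part_11	RV	TCAGGTGACGCTCATTTCCT	7303-7284
LJV_Part_12	FW	TCCCGGCATCTCAAAGTGAA	7199-7218
LJV_Part_12	RV	AGGTAAGTGCATTTTGGCCG	7947-7947
LJV_Part_13	FW	TGAAGTTTCCGGTAAGTGCG	7869-7888
LJV_Part_13	RV	AAAGGAGATGCGCAGAACAC	8576-8557
LJV_Part_14	FW	TCCTGAAGTTGCGAACCAGA	8421-8440
LJV_Part_14	RV	TCGCCGTAAACATACATGCA	9134-9115
LJV_Part_15	FW	GGTGAAGGAAAATGGCGTGA	9079-9098
LJV_Part_15	RV	TGGATGTGGCACGAAATTACA	9312-9292
LJV_RACE_1	RV	GGATTCCAAGAGGTAGTCCCGTGAAC	241-216
LJV_RACE_2	RV	CTTTTAGGTGTGGTAGAGTATCATG	153-129
T1		GGCCACGCGTCGACTAGTACTTTTTTTTTTTTTTTTT	oligo-dT
T2		GGCCACGCGTCGACTAGTACGGGGGGGGGGGGGG	adapter
T22		GGCCACGCGTCGACTAGTAC	adapter
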