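chromosome	position	subfamily	orientation	tsd_length	tsd_sequence	polya_length	polya_impurity
chr1_hap1	32597902	AluY	Sense	18	AAAAAAAATTAGCTGGGC	42	0.00
chr1_hap1	84167056	AluY	Sense	16	AAAAACTCACAAGTGG	57	0.00
chr1_hap1	135602742	AluY	Sense	17	ATAAAGCAGCAGAACTG	41	0.00
chr1_hap1	176727588	AluYa5	Sense	11	AAGAATGTTGA	24	0.04
chr2_hap1	170690878	AluYa5	Antisense	13	GACCTCATTTCTA	39	0.08
chr2_hap1	198786241	AluYa5	Antisense	18	GGAAAATCATTAACTTTA	42	0.00
chr3_hap1	36808900	AluYc	Antisense	11	GAAATCAGTCT	28	0.00
chr4_hap1	68633195	AluYa5	Antisense	14	CAACTTTGGTTTTT	99	0.00
chr4_hap1	104523183	AluYg6	Sense	15	GAAAATGCTAAAGGC	79	0.00
chr4_hap2	65226148	AluYa5	Sense	17	AAAAAGACACTAATTTA	79	0.00
chr6_hap1	47771164	AluYb8	Antisense	18	GATGACAGCTTAACTCTT	119	0.00
chr6_hap1	60438603	AluY	Antisense	12	GATAGAGCAGTT	42	0.14
chr6_hap1	91253973	AluY	Antisense	12	CACAAGCATTCT	34	0.00
chr6_hap1	91909369	AluYk2	Sense	9	AAGATTATA	57	0.00
chr6_hap1	103729153	AluYa5	Sense	14	AAAAAATATTGATC	80	0.00
chr6_hap1	170029052	AluYb8	Antisense	18	GGTAATCTTCCAGATTCT	31	0.00
chr6_hap2	76108804	AluYb8	Sense	16	AGAAAGCATGAAGCTG	73	0.00
chr6_hap2	148611276	AluYb8	Antisense	13	AGCACCATTTATT	40	0.18
chr7_hap2	90506402	AluYa5	Antisense	17	ATGTGCCACATTTTCTT	83	0.00
chr8_hap1	18412380	AluYb8	Antisense	17	AAAAGTTCTTTTTTTCT	79	0.00
chr8_hap1	135685705	AluYa5	Antisense	8	AACCTTCT	42	0.00
chr8_hap2	42738991	AluYa5	Antisense	10	TAAGGTAGCT	55	0.00
chr8_hap2	51723185	AluYk2	Sense	12	AAAGACACATGC	26	0.00
chr8_hap2	92608133	AluYb9	Sense	17	AAAAATATGGAAAGTCA	35	0.00
chr8_hap2	127839152	AluYa5	Sense	15	GAAAACTGGCACAAG	29	0.03
chr10_hap1	115958422	AluYa5	Antisense	16	CTGCCACTCCTCCTTT	64	0.00
chr10_hap2	9718078	AluYa5	Sense	12	GAAGAAGAGAGA	25	0.00
chr10_hap2	74978969	AluYa5	Sense	15	AAAGACTACAAATTG	50	0.00
chr11_hap1	137478201	AluY	Sense	11	GAAAACATACA	83	0.00
chr11_hap2	90051026	AluYb8	Antisense	15	GGGATTGGCTTTTAT	92	0.00
chr12_hap1	20298293	AluYa5	Antisense	15	TTATTTGTATTTTTT	55	0.00
chr12_hap2	85693478	AluYk2	Antisense	15	TTTTTTTTGCTTCTT	147	0.00
chr12_hap2	127435699	AluYk12	Antisense	9	CTGTTTCTT	28	0.07
chr12_hap2	128464422	AluYe5	Sense	14	AAAAGAAATAAAAG	59	0.00
chr13_hap1	36254334	AluYa5	Antisense	14	GAGACCCCATCTCT	38	0.00
chr13_hap2	82636190	AluYh7	Antisense	15	AATTTTTATTTTTTT	20	0.00
chr14_hap1	8559263	AluYb8	Sense	15	AAAAAGTCTGTTTCC	51	0.00
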