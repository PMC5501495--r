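name	direction	adapter	barcode	spacer	priming	full_oligo
f1	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CACGCTGTATAC		GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCACGCTGTATACGTGYCAGCMGCCGCGGTAA
f2	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CCCAGCGGAGAA	A	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCCCAGCGGAGAAAGTGYCAGCMGCCGCGGTAA
f3	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	GGCAGGTACTGA	GA	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTGGCAGGTACTGAGAGTGYCAGCMGCCGCGGTAA
f4	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	TGATCTCTCCTT	TAA	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTTGATCTCTCCTTTAAGTGYCAGCMGCCGCGGTAA
f5	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	TGTAACTGGTGT	GGAA	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTTGTAACTGGTGTGGAAGTGYCAGCMGCCGCGGTAA
f6	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CTGATGTTAAAG	TACAA	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCTGATGTTAAAGTACAAGTGYCAGCMGCCGCGGTAA
f7	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	GGTGCTCGCGCG	GGTTAT	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTGGTGCTCGCGCGGGTTATGTGYCAGCMGCCGCGGTAA
f8	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CGTATTCGATAG	GCTACAT	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCGTATTCGATAGGCTACATGTGYCAGCMGCCGCGGTAA
f9	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	ATGCTACCACTT		GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTATGCTACCACTTGTGYCAGCMGCCGCGGTAA
f10	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	CAAGAAGGGAGC	C	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTCAAGAAGGGAGCCGTGYCAGCMGCCGCGGTAA
f11	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	TTCCCGGGCAAC	AA	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTTTCCCGGGCAACAAGTGYCAGCMGCCGCGGTAA
f12	forward	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	GTGATCTAGGAC	ATG	GTGYCAGCMGCCGCGGTAA	ACACTCTTTCCCTACACGACGCTCTTCCGATCTGTGATCTAGGACATGGTGYCAGCMGCCGCGGTAA
r1	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	ATAATATCTCAC		GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTATAATATCTCACGGACTACNVGGGTWTCTAAT
r2	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	TAATATATGCTA	C	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTAATATATGCTACGGACTACNVGGGTWTCTAAT
r3	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	GACTGTTCCACA	AC	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGACTGTTCCACAACGGACTACNVGGGTWTCTAAT
r4	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	TCTTACCTTCAG	GCG	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTCTTACCTTCAGGCGGGACTACNVGGGTWTCTAAT
r5	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	GCAACTGCTGCG	CCCA	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGCAACTGCTGCGCCCAGGACTACNVGGGTWTCTAAT
r6	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	TGTAAGCCGGTG	CTCGT	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTTGTAAGCCGGTGCTCGTGGACTACNVGGGTWTCTAAT
r7	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	ATTTATCCTAAC	GATTCA	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTATTTATCCTAACGATTCAGGACTACNVGGGTWTCTAAT
r8	reverse	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	GGTACCAAAGGG	CCTTAGT	GGACTACNVGGGTWTCTAAT	GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGGTACCAAAGGGCCTTAGTGGACTACNVGGGTWTCTAAT
pcr2f	pcr2_forward	AATGATACGGCGACCACCGAGATCTACAC			ACACTCTTTCCCTACACGACGCTCTTCCGATCT	AATGATACGGCGACCACCGAGATCTACACACACTCTTTCCCTACACGACGCTCTTCCGATCT
p1	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	CATGAC		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATCATGACGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p2	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	TAGATT		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATTAGATTGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p3	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	CGCTCG		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATCGCTCGGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p4	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	TCGGAT		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATTCGGATGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p5	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	AGAGAC		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATAGAGACGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p6	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	GTTACA		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATGTTACAGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p7	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	CCTAAA		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATCCTAAAGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p8	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	CAATGG		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATCAATGGGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p9	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	ACACAA		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATACACAAGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p10	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	AGGTGG		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATAGGTGGGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p11	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	TTAGCT		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATTTAGCTGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
p12	pcr2_reverse	CAAGCAGAAGACGGCATACGAGAT	CAGAGA		GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT	CAAGCAGAAGACGGCATACGAGATCAGAGAGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT
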