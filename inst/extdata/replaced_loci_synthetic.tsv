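population	gene	strong_selection	ancestor	donor	recipient	recombinant
Ara+1	arcA	Yes	AAACTC	AAACAC	ACACTC	AAACAC
Ara+1	hslU	Yes	CTCCGGAAGT	CTCCGCAAGT	CTCCTGAAGT	CTCTGCAAGT
Ara+1	ycfC	No	ACTCGGC	ACTCGGC	AGTCGGC	ACTCGGC
Ara+1	yecE	No	ATATCTC	ATATCTC	ATTTCTC	ATATCTC
Ara+4	infB	Yes	ACCCCC	ACCCCC	ACCTCC	ACCCCC
Ara+4	mreB	Yes	CGCCCTAAAG	CGCCCTAAAG	CGCACTAAAG	CGCCCTAAAG
Ara+4	spoT	Yes	AATTAGG	AATCAGG	AATTCGG	AATCAGG
Ara+5	rplF	Yes	TCCCTACACT	TCCCTACACT	TCCCTAAACT	TCCCTACACT
Ara+5	rpsC	No	ATGCCGAAC	ATGCCGAAC	ATCCCGAAC	ATGCCGAAC
Ara+5	yhdG	Yes	AATAAACGA	AATAAACGA	AATAAACAA	AATAAACGA
Ara-1	malT	Yes	ACAAGT	ACGAGT	ATAAGT	ACGAGT
Ara-1	rpsM	No	GAAAGG	GAAAGG	CAAAGG	GAAAGG
Ara-1	yghJ	No	CATATCAC	CATATGAC	CATATCGC	CATATGAG
Ara-3	fis	No	TGCCGTCTT	TGCCGTCTT	TGCCGTCTA	TGCCGTCTT
Ara-3	hslU	Yes	TTCATGA	TTCATGA	TTCATCA	TTCATGA
Ara-3	malT	Yes	TCGTGCA	TCGTGGA	TCGCGCA	TCGTGGA
Ara-3	mrdB	No	AAGCCT	AAGCCT	ACGCCT	AAGCCT
Ara-3	pykF	Yes	GCCGGAGTCT	GCCGGAGTCT	TCCGGAGTCT	GCCGGAGTCT
Ara-3	rpsG	No	CTTTGAAA	CTTTGAAG	CTTTGCAA	CTTTGAAG
Ara-3	tdcR	No	GAATAAATC	GAATAAATC	GAATAAAGC	GAATAAATC
Ara-3	topA	Yes	AATACGTG	AATACGTG	AATATGTG	AATACGTG
Ara-4	garP	No	GGAAAGC	GGAAAGC	GGAATGC	GGAAAGC
Ara-4	infA	No	TGAATATCT	TGAATATCT	AGAATATCT	TGAATATCT
Ara-4	mreB	Yes	ACCCCTGC	ACCCCTGC	ACCCCTCC	ACCCCTGC
Ara-4	nadR	Yes	AGGACACACT	AGTACACACT	TGGACACACT	AGGACACACT
Ara-4	pykF	Yes	CCTTGAG	CCTTGAA	TCTTGAG	CCTTCAA
Ara-4	spoT	Yes	AGTCCAG	AGACCAG	AGTCCAC	AGTCCAG
Ara-4	ydfI	No	GTATCCAC	GTATCCTC	GTCTCCAC	GTATCCAC
Ara-4	ypdC	No	TACGACTCGG	TACGACTCGA	TACGTCTCGG	TACGACTCGG
Ara-5	ybaL	Yes	CGCGCGGTTT	CGCGCGGTTT	CGCGGGGTTT	CGCGCGGTTT
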