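code	name_fwd	name_rev	seq_fwd	seq_rev	ref_start	ref_end
a	RHOSE	RHOAS	ACGGSCAYTTCTACRTCG	CCGTAARTGYTCGAGRTAG	481	823
b	Rh alkB1-F2	Rh alkB1-R1	ATCTGGGCGCGTTGGGATTTGAGCG	CGCATGGTGATCGCTGTGCCGCTGC	331	950
c	Rh alkB2-F2	Rh alkB2-R1	ACTTTGGCGCAGTCGTTTTACGGCC	CCCACTGGGTAGGTTGGGCGCACCG	462	1013
d	alkF	alkR	GCICAIARITIRKICAYAA	GCITGITGITCISWRTGICGYTG	408	949
e	alkB-1f	alkB-1r	AAYCANGCNCAYGARCTNGGNCAYAA	GCRTGRTGRTCNGARTGNCGYTG	402	949
f	alk-H1F	alk-H3R	CIGIICACGAIITIGGICACAAGAAGG	IGCITGITGATCIIIGTGICGCTGIAG	406	950
g	AlkBF	AlkBR	CCTGCTCCCGATCCTCGA	TCGTACCGCCCGCTGTCCAG	170	911
h	Alk-BFB	Alk-BRB	GGTACGGSCAYTTCTACRTCGA	CGGRTTCGCGTGRTGRT	477	956
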