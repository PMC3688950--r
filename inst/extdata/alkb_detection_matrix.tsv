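strain	group	taxon	hep	a	b	c	d	e	f	g	h
Ari_O 5A	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	+	-	-	+
Ari_O 8	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	+	-	-	+
Br_lB 66	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	-	-	-	+
Br_lB 68	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	-	-	+	+
Bri_O 66	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	-	-	-	+
Cri_O 3	Gammaproteobacteria	Acinetobacter baumannii	+	-	-	-	+	+	+	-	+
Ari_O 10	Gammaproteobacteria	Acinetobacter calcoaceticus	+	+	-	-	+	+	+	-	-
Ari_O 20	Gammaproteobacteria	Acinetobacter oleivorans	+	-	-	-	+	-	-	-	-
Ari_O 1	Gammaproteobacteria	Enterobacter gergoviae	+	-	+	-	+	-	-	-	-
Br_O 3B	Gammaproteobacteria	Pseudomonas aeruginosa	+	-	+	-	-	+	-	+	-
Ar_lB 45B	Gammaproteobacteria	Pseudomonas aeruginosa	+	-	+	-	-	+	-	+	-
Br_O 5A.1	Gammaproteobacteria	Pseudomonas aeruginosa	+	-	+	-	-	+	-	-	-
Ar_lB 49	Gammaproteobacteria	Pseudomonas sp. Bu34	+	-	+	-	-	+	-	-	-
Ar_lB 50B	Gammaproteobacteria	Pseudomonas sp. Bu34	+	-	+	-	-	+	-	+	-
Br_lB N1B	Gammaproteobacteria	Stenotrophomonas maltophilia	+	-	-	+	-	-	+	-	+
PBL 3.1	Gammaproteobacteria	Stenotrophomonas sp.	+	-	+	+	-	-	-	-	-
EM	Betaproteobacteria	Burkholderia seminalis	+	-	-	+	-	+	+	-	+
Bri_O 42B	Betaproteobacteria	Cupriavidus gilardii	+	-	-	-	-	-	-	-	-
Bri_O 51	Betaproteobacteria	Cupriavidus sp. C14	+	-	-	-	-	-	-	-	-
Ar_lB N1	Betaproteobacteria	Pandoraea sp. KBA1SM3	+	-	+	-	-	-	+	-	-
Cr_lB N2B.1	Alphaproteobacteria	Agrobacterium tumefaciens	+	-	-	-	-	+	-	+	+
Cr_O 46.1	Alphaproteobacteria	Bosea minatitlanensis	+	-	-	-	-	-	-	-	-
Cr_O 49.2	Alphaproteobacteria	Bosea minatitlanensis	+	-	-	+	-	-	-	-	-
Ari_O 50	Alphaproteobacteria	Mycoplana bullata	+	-	-	-	-	-	+	-	-
Cr_lB 49A	Alphaproteobacteria	Rhizobium sp. JNVU TL9	+	-	-	-	-	-	-	-	-
Cr_lB N4A	Alphaproteobacteria	Rhizobium sp. VL-2	+	-	-	-	-	+	-	+	-
Bri_O 61	Flavobacteria	Chryseobacterium daecheongense	+	-	-	-	+	-	-	-	+
Cr_lB N2B.2	Firmicutes	Bacillus cereus	+	-	-	-	-	-	-	-	-
Cr_lB 43	Firmicutes	Bacillus cereus	+	-	-	-	-	-	-	-	-
P4	Actinomycetales	Dietzia cinnamea	+	-	-	-	-	+	+	-	+
Bri_O 50	Actinomycetales	Gordonia amicalis	+	+	-	-	-	+	+	+	-
Cr_O 47	Actinomycetales	Gordonia amicalis	+	-	-	-	-	+	+	-	-
LBOa 3.2	Actinomycetales	Gordonia alkanivorans	+	-	-	-	-	-	-	-	-
DTSB 2.5	Actinomycetales	Gordonia rubriperctinta	+	-	-	+	-	-	+	+	+
DLB 1.9	Actinomycetales	Nocardia veterana	+	+	-	-	-	-	+	-	-
Ari_O Alk	Actinomycetales	Rhodococcus equi	+	-	-	-	-	-	+	-	+
Bri_lB 51	Actinomycetales	Rhodococcus equi	+	+	-	-	-	+	+	-	+
Cr_lB 46A	Actinomycetales	Rhodococcus equi	+	+	-	+	-	+	+	-	+
Cr_lB 47B	Actinomycetales	Rhodococcus equi	+	-	-	+	-	+	+	-	-
Cr_lB 93	Actinomycetales	Rhodococcus equi	+	+	-	+	-	+	+	-	+
DLB 1.4	Actinomycetales	Rhodococcus equi	+	-	-	-	-	-	+	-	+
DLB 3.4	Actinomycetales	Rhodococcus sp. PA	+	+	-	-	-	+	+	-	+
DTSB 3.5	Actinomycetales	Rhodococcus sp. DASAN	+	+	-	+	-	+	+	-	+
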