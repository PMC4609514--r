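# Benchmark of published human promoter variants inside or near TBP-binding
# sites, compiled from the primary literature on regulatory SNPs scored by
# the three-step TBP-affinity model. Each row gives the 21-bp promoter
# context printed in the source reports (10-bp flanks around the variant
# base(s)), the TSS-relative position of the variant, the reported
# dissociation constants (nM) of the minor and ancestral (hg19) alleles,
# the reported direction of the expression change for the minor allele
# (up = overexpression/affinity gain, down = deficiency/affinity loss,
# eq = no significant change), and the reported Z-score and significance.
# Multi-allelic rows are represented by their first listed minor allele.
# "." denotes an empty ref (insertion) or alt (deletion).
gene	label	notation	kind	position	flank5	ref	alt	flank3	kd_minor_nM	kd_ancestral_nM	arrow	z_reported	alpha_reported
IL1B	rs1143627	-31c>t	sub	-31	ttttgaaagc	C	T	ataaaaacag	2	5	up	15	1e-7
IL1B	rs549858786	-28a>t	sub	-28	tgaaagccat	A	T	aaaacagcga	7	5	down	8	1e-7
F3	rs563763767	-21c>t	sub	-21	ccctttatag	C	T	gcgcggggca	2	3	up	6	1e-7
NOS2	NOS2_-51t>c	-51t>c	sub	-51	gtataaatac	T	C	tcttggctgc	1	2	up	3	1e-2
DHFR	rs10168	-26g>a	sub	-26	ctgcacaaat	G	A	gggacgaggg	9	15	up	9	1e-7
PGR	rs10895068	-26g>a	sub	-26	gggagataaa	G	A	gagccgcgtg	6	10	up	8	1e-7
PGR	rs544843047	-33t>c	sub	-33	agtcgggaga	T	C	aaaggagccg	22	10	down	14	1e-7
CYP21A2	CYP21A2_-20a>t	-20a>t	sub	-20	gtcattccag	A	T	aaagggccac	13	24	up	9	1e-7
TNFRSF18	rs111426889	-25c>t	sub	-25	gtgctataaa	C	T	gccgccccct	2	4	up	8	1e-7
HBB	rs397509430	del-29t	del	-29	gggctgggca	T	.	atacaacagt	29	5	down	34	1e-7
HBB	rs33980857	-29t>a	sub	-29	gggctgggca	T	A	atacaacagt	21	5	down	27	1e-7
HBB	rs34598529	-28a>g	sub	-28	ggctgggcat	A	G	aaagtcaggg	18	5	down	24	1e-7
HBB	rs33931746	-27a>g	sub	-27	gctgggcata	A	G	aagtcagggc	11	5	down	14	1e-7
HBB	rs33981098	-30a>g	sub	-30	agggctgggc	A	G	taaaagtcag	9	5	down	10	1e-7
HBB	rs34500389	-31c>a	sub	-31	cagggctggg	C	A	ataaaagtca	6	5	down	3	1e-2
HBB	HBB_-27a>t	-27a>t	sub	-27	gctgggcata	A	T	aagtcagggc	3	5	up	8	1e-2
HBB	rs63750953	del-25aa	del	-25	ctgggcataa	AA	.	gtcagggcag	8	5	down	9	1e-7
HBB	rs281864525	-25a>c	sub	-25	tgggcataaa	A	C	gtcagggcag	7	5	down	7	1e-7
HBD	rs35518301	-31a>g	sub	-31	caggaccagc	A	G	taaaaggcag	8	4	down	11	1e-7
HBD	rs34166473	-30t>c	sub	-30	aggaccagca	T	C	aaaaggcagg	8	4	down	18	1e-7
DARC	rs2814778	-26t>c	sub	-26	ttggctctta	T	C	cttggaagca	12	10	down	4	1e-3
DARC	rs55878706	-27a>t	sub	-27	cttggctctt	A	T	tcttggaagc	12	10	down	4	1e-3
CYP2A6	rs28399433	-34t>g	sub	-34	tcaggcagta	T	G	aaaggcaaac	9	2	down	21	1e-7
CRYGEP	rs55999272	-28t>c	sub	-28	tcctgctata	T	C	agccccgccg	5	2	down	11	1e-7
MMP12	rs2276109	-27a>g	sub	-27	gatatcaact	A	G	tgagtcactc	14	11	down	3	1e-2
MMP12	rs572527200	-30a>g	sub	-30	gatgatatca	A	G	ctatgagtca	14	11	down	3	1e-2
CETP	rs17231520	-68g>a	sub	-68	ggggctgggc	G	A	gacatacata	2	4	up	10	1e-7
CETP	rs569033466	-53g>a	sub	-53	atacatatac	G	A	ggctccaggc	3	4	up	4	1e-3
CYP2B6	rs34223104	-28t>c	sub	-28	gatgaaattt	T	C	ataacagggt	10	4	down	15	1e-7
CYP2B6	rs563558831	-26t>c	sub	-26	tgaaatttta	T	C	aacagggtgc	10	4	down	13	1e-7
SOD1	rs7277748	-32a>g	sub	-32	ggtctggcct	A	G	taaagtagtc	7	2	down	17	1e-7
TPI1	rs1800202	-24t>g	sub	-24	gcgctctata	T	G	aagtgggcag	4	1	down	17	1e-7
ESR2	rs35036378	-43t>g	sub	-43	cctctcggtc	T	G	ttaaaaggaa	8	6	down	5	1e-3
HSD17B1	rs201739205	-36a>c	sub	-36	aggtgatatc	A	C	agcccagagc	18	13	down	5	1e-3
MBL2	rs72661131	-39t>c	sub	-39	tctatttcta	T	C	atagcctgca	4	2	down	12	1e-7
MBL2	rs562962093	-40a>g	sub	-40	atctatttct	A	G	tatagcctgc	5	2	down	15	1e-7
MBL2	rs72661131_35	-35g>a	sub	-35	tttctatata	G	A	cctgcaccca	1	2	up	12	1e-7
ADH7	rs17537595	-36t>c	sub	-36	gctgctgtta	T	C	atacaacaga	3	1	down	13	1e-7
ADH7	rs372329931	-37a>g	sub	-37	agctgctgtt	A	G	tatacaacag	3	1	down	13	1e-7
APOA1	APOA1_-35a>c	-35a>c	sub	-35	tgcagacata	A	C	ataggccctg	4	3	down	5	1e-3
F7	F7_-33a>c	-33a>c	sub	-33	ccttggaggc	A	C	gagaactttg	62	53	down	3	1e-2
F7	rs367732974	-19g>a	sub	-19	aactttgccc	G	A	tcagtcccat	47	53	up	2	0.05
F7	rs549591993	-13c>a	sub	-13	gcccgtcagt	C	A	ccatggggaa	25	53	up	13	1e-7
FSHR	rs1394205	-29g>a	sub	-29	gcaaatgcag	G	A	aagaaatcag	7.3	7.3	eq	0	0.05
F9	F9_-48g>c	-48g>c	sub	-48	agctcagctt	G	C	tactttggta	6.4	6.4	eq	0	0.05
F9	F9_-42t>a	-42t>a	sub	-42	gcttgtactt	T	A	ggtacaacta	6.4	6.4	eq	0	0.05
F9	rs371045754	-32a>c	sub	-32	tggtacaact	A	C	atcgacctta	9.6	6.4	down	5	1e-7
StAR	rs16887226	-33c>t	sub	-33	cagccttcag	C	T	gggggacatt	10.3	10.3	eq	0	0.05
StAR	rs544850971	-22a>g	sub	-22	tcagcggggg	A	G	catttaagac	12.1	10.3	down	5	1e-2
GH1	rs28399433_GH1	del-50g	del	-50	aggggccagg	G	.	tataaaaagg	1.4	1.5	eq	1	0.05
GSTM3	rs1332018	-49c>a	sub	-49	ccccttatgt	C	A	gggtataaag	3.1	3.6	eq	1.9	0.05
GSTM3	rs200209906	-36c>t	sub	-36	gtataaagcc	C	T	ctcccgctca	4.3	3.6	down	2.4	0.05
UGT1A7	rs7586110	-57t>g	sub	-57	cttcttccac	T	G	tactatatta	1.48	1.54	eq	1	0.05
UGT1A7	rs574890114	-55a>g	sub	-55	tcttccactt	A	G	ctatattata	2.02	1.54	down	4	1e-3
UGT1A7	rs542729995	-52a>g	sub	-52	tccacttact	A	G	tattatagga	2.28	1.54	down	5	1e-7
GJA5	rs10465885	-55g>a	sub	-55	caactaagat	G	A	tattaaacac	3.1	3.4	eq	1	0.05
GJA5	rs35594137	-39g>a	sub	-39	gaggagggaa	G	A	gcgacagata	5.7	5.7	eq	0	0.05
GJA5	rs587745372	-29a>t	sub	-29	ggcgacagat	A	T	cgattaaaaa	6.8	5.7	down	3	1e-3
THBD	rs13306848	-33g>a	sub	-33	agggagggcc	G	A	ggcacttata	2.3	2.1	eq	1	1e-7
UGT1A1	rs34983651	ins-55at	ins	-55	ggtttttgcc	.	AT	atatatatat	0.65	0.67	eq	1	0.05
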