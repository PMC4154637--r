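# NRP mass-shift conversion table, v1 (monoisotopic residue masses, Da)
# Reconstructed from standard residue masses; users may replace this file.
# Columns: mass <TAB> candidate monomers ("/"-joined) <TAB> label
# Isobaric monomers share a row; near-isobaric rows are merged at query
# time by the mass tolerance.
mass	candidates	label
57.02146	gly	Gly
71.03711	ala	Ala
85.05276	abu/iva	2-aminobutyrate / isovaline (isobaric)
87.03203	ser	Ser
97.05276	pro	Pro
99.06841	val	Val
100.06366	dab	2,4-diaminobutyrate
101.04768	thr/allothr	Thr / allo-Thr (isobaric)
101.08406	vol	valinol
103.00919	cys	Cys
111.06841	pip	pipecolate
113.08406	ile/leu	Ile / Leu (isobaric, Xle)
114.04293	asn	Asn
114.07931	orn	ornithine
115.02694	asp	Asp
120.02113	sal	salicylate
128.05858	gln	Gln
128.09496	lys	Lys
129.04259	glu	Glu
131.04049	met	Met
136.01604	dhb	2,3-dihydroxybenzoate
137.05891	his	His
143.05824	aad	2-aminoadipate
147.06841	phe	Phe
149.04768	hpg	4-hydroxyphenylglycine
156.10111	arg	Arg
163.06333	tyr	Tyr
165.04259	dhpg	3,5-dihydroxyphenylglycine
177.07898	hty	homotyrosine
179.05824	bht	beta-hydroxytyrosine
186.07931	trp	Trp
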