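# RiPP mass-shift conversion table, v1 (monoisotopic residue masses, Da)
# Reconstructed, PTM-aware: thioether-crosslinked Cys in lanthionine rings
# reads at the Ala (or dehydrated Ser) mass, so those rows carry Cys as an
# extra candidate; Ile/Leu are strictly isobaric; Lys/Gln merge only at
# low resolution via the query-time tolerance. Users may replace this file.
# Columns: mass <TAB> candidate monomers ("/"-joined) <TAB> label
mass	candidates	label
57.02146	gly	Gly
69.02146	ser/cys	dehydroalanine (Dha, from Ser; or lanthionine Cys)
71.03711	ala/cys	Ala (or lanthionine-linked Cys)
83.03711	thr	dehydrobutyrine (Dhb, from Thr)
87.03203	ser/cys	Ser (or oxidized/linked Cys)
97.05276	pro	Pro
99.06841	val	Val
101.04768	thr	Thr
103.00919	cys	Cys
113.08406	ile/leu	Ile / Leu (isobaric, Xle)
114.04293	asn	Asn
115.02694	asp	Asp
128.05858	gln	Gln
128.09496	lys	Lys
129.04259	glu	Glu
131.04049	met	Met
137.05891	his	His
147.06841	phe	Phe
156.10111	arg	Arg
163.06333	tyr	Tyr
186.07931	trp	Trp
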