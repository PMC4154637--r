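# NORINE-style monomer frequency table -- SYNTHETIC snapshot, v1
# Constructed background frequencies of monomer occurrences in known
# nonribosomal peptides; not exported from the live NORINE database.
# The alphabet of the scorer is exactly the set of monomers listed below
# (proteinogenic amino acids plus common nonproteinogenic NRP monomers);
# counts are occurrence counts, smoothed at query time with pseudocount k.
monomer	count
ala	296
arg	118
asn	131
asp	286
cys	104
gln	125
glu	229
gly	287
his	52
ile	189
leu	420
lys	117
met	41
phe	172
pro	226
ser	343
thr	313
trp	48
tyr	164
val	304
orn	146
dab	77
abu	64
iva	39
pip	46
hpg	71
dhpg	58
bht	33
hty	27
allothr	31
vol	14
aad	36
dhb	61
sal	22
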