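---
title: "Matching MS-derived peptide tags to biosynthetic gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching MS-derived peptide tags to biosynthetic gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pep2path)
```

## The problem

Tandem mass spectrometry can read short amino-acid *sequence tags* out of
peptidic natural products: the mass differences between consecutive
fragment-ion peaks correspond to monoisotopic residue masses, so a ladder
of peaks yields an ordered list of residues. Because several residues are
isobaric (Ile/Leu always; Lys/Gln at modest resolution; Thr/allo-Thr among
the nonproteinogenic monomers), a tag is in general *degenerate*: each
position carries a set of candidate monomers, written `I(L)` or
`T(S)` in the conventional notation.

Linking such a tag back to the biosynthetic gene cluster (BGC) that makes
the peptide is the slow, manual step this package automates, separately
for the two big peptide classes:

* **Nonribosomal peptides (NRPs)** are assembled by nonribosomal peptide
  synthetases (NRPSs), giant multi-modular enzymes in which each module's
  adenylation (A) domain selects one monomer. Sequence-based predictors
  give, per module, a *Stachelhaus code* (the ~10 active-site residues,
  with a fractional identity to the closest experimentally characterized
  code) and nested SVM class predictions at four granularities. Matching
  a tag to a BGC means asking: could this chain of predicted substrate
  specificities, in some order, have produced this residue sequence?
* **RiPPs** (ribosomally synthesized and post-translationally modified
  peptides) are genome-encoded, so the core peptide can be looked up
  directly in the six translation frames of the genome.

## The NRP scoring model

For a tag position with residue (set) $A$ aligned to a module $M$, we
score the log-likelihood ratio

$$ s(A, M) \;=\; \ln \frac{P(A \mid M)}{P(A)} , $$

so that a module predicting the observed residue rewards the alignment
and an uninformative module contributes nothing. A flat prior over
modules is assumed throughout (a nonuniform prior would matter for, say,
community samples where organism abundance differs; estimating it is out
of scope here).

**Background probability.** $P(A)$ is the probability of seeing monomer
$A$ in a nonribosomal peptide at all, estimated from background
occurrence counts $n_A$ over an alphabet $\Sigma$ with additive
smoothing:

$$ P(A) = \frac{n_A + k}{N + k\,|\Sigma|}, \qquad N = \sum_A n_A , $$

with pseudocount $k = 1$ correcting for the limited size of the
background sample. For a *degenerate* position the fixed baseline
$1/|\Sigma|$ is used instead of any candidate's frequency: a merely
possible rare monomer must not be treated as an actual observation of a
rare monomer, which would bias scores towards matches on rare residues.

The package ships a NORINE-style background table
(`monomer_frequencies_synthetic.tsv`). It is a **constructed snapshot**
with realistic relative abundances over 34 monomers (20 proteinogenic +
14 common nonproteinogenic), not an export of any curated database; the
file format is documented and users with curated counts should replace
it via `readFrequencyTable()`.

**Prediction match value.** Each candidate monomer $a$ of the position is
compared with the module's two prediction channels. The SVM channel
contributes the innermost matching tier — 1.0 (single-residue
prediction), 0.75 (small class), 0.5 (large class), 0.25 (three-class),
0.0 (no tier matches; no-call predictions are empty sets and can match
nothing). The Stachelhaus channel contributes the fractional code
identity when $a$ is among the monomers loaded by the closest known
code, and 0 otherwise — identity is only reported against the nearest
known code, so non-best-match candidates get no partial credit. $I(a)$
is the mean of the two channels; when a prediction carries only one
channel, that channel stands alone rather than being averaged with an
artificial zero. The position's match value is
$\bar I = \max_a I(a)$: a degenerate tag is compatible with its
best-matching reading.

**Conditional probability.** $P(A \mid M)$ blends the prediction with the
background:

$$ P(A \mid M) \;=\; \frac{c\,\bar I^{\eta} + x\,P(A)}{c + x} , $$

chosen as the simplest form with the behaviour the model needs:

* the confidence factor $c \ge 0$ (default 1) weighs predictions against
  the background; at $c = 0$ every term is exactly $\ln 1 = 0$ and
  scoring is baseline-neutral;
* the pseudocount $x \in (0, 1]$ (default 0.01) keeps complete
  mismatches finite: at $\bar I = 0$ the term is $\ln\!\big(x/(c+x)\big)
  \approx -4.62$ at the defaults, independent of $P(A)$;
* the exponent $\eta \ge 1$ (default 2) sharpens the penalty for partial
  mismatches; because the cluster score is a *sum* of logs, penalties
  grow exponentially with the number of mismatched positions. The term
  is $\eta$-invariant at $\bar I \in \{0, 1\}$ and strictly increasing
  in $\bar I$ for $c > 0$ — all four limits are locked by tests.

**Cluster score.** A BGC's genes may act in any order in the assembly
line, while modules within one gene keep their native order — assembly
lines are colinear at the protein level, and permuting individual
modules would both contradict that biology and explode combinatorially.
`enumerateOrderings()` therefore permutes whole genes only (lexicographic
generation order, truncated deterministically at `maxOrderings`, default
$5040 = 7!$, with a `capped` flag on the result). The cluster score is

$$ S(C \mid T) \;=\; \max_{\text{alignments}} \sum_{i} s(A_i, M_{\pi(i)}) $$

over all gene orderings, all contiguous gap-free offsets of the tag
along the concatenated module sequence, and both tag orientations by
default — fragmentation does not reveal the N-to-C reading direction
(`orientationMode = "forward"` disables the reversed reading). A tag
longer than the module chain has no admissible alignment and receives
the sentinel $-\infty$, which always ranks last.

**Colinearity index.** To help interpret near-ties, each best alignment
carries the fraction of adjacent tag-position pairs whose modules are
native-consecutive within one gene in ascending order (length-1
alignments score 1 by convention; a reversed in-gene alignment scores
0). Ranking sorts by $S$, breaks ties by higher colinearity and then by
cluster id, and *shares* ranks when both $S$ and the index tie —
orthologous clusters in related genomes legitimately produce identical
best hits, and a shared first place is a successful identification.
Exact score ties between alignments inside one cluster are resolved
toward the higher colinearity index, then by enumeration order
(orderings, then offsets, then forward before reversed), which makes
results reproducible bit-for-bit.

## Tunable parameters

| parameter | default | units / range | meaning |
|---|---|---|---|
| `c` | 1 | $\ge 0$ | confidence in predictions vs background |
| `x` | 0.01 | (0, 1] | mismatch pseudocount (score floor) |
| `eta` | 2 | $\ge 1$ | mismatch-penalty exponent |
| `k` | 1 | $\ge 0$ | background smoothing pseudocount |
| `orientationMode` | NRP `"both"`, RiPP `"forward"` | — | tag reading direction(s) |
| `maxOrderings` | 5040 | $\ge 1$ | cap on gene permutations |
| mass tolerance | 0.02 | Da | conversion-table matching window |
| expansion cap | 10000 | sequences | guard on degenerate-tag expansion |

The 0.02 Da tolerance reflects typical high-resolution MS tag accuracy
and is CLI-overridable (`--tolerance`); at 0.05 Da Lys/Gln collapse into
one degenerate position, which is the intended behaviour for
lower-resolution data. The RiPP orientation default is `"forward"` as
the conservative reading — per-genome match counts are
orientation-sensitive, and `"both"` can be requested explicitly.

## Mass conversion tables

`massesToTag()` turns an ordered mass-shift list into a degenerate tag by
collecting the union of candidates of all table rows within the
tolerance. Two editable tab-separated tables ship under `extdata`: an
NRP table (31 rows over the 34-monomer alphabet, strictly isobaric
residues sharing rows) and a PTM-aware RiPP table in which
dehydration/thioether chemistry makes lanthionine-linked Cys read at
Ala/Ser-like masses. Both are versioned, best-effort reconstructions of
the residue-mass bookkeeping practitioners use, and are meant to be
replaced wholesale when a curated table is available.

## RiPP matching

`sixFrameTranslate()` translates all three frames of both strands with
the bacterial/archaeal code (translation table 11; frames are windows,
not ORFs, so no initiation-codon special-casing is applied). Stop codons
become `*` and N-containing codons `X`; neither symbol matches any
candidate, so matching windows can never span a stop or an ambiguous
codon — precursor peptides are contiguous ORF content. No
start-codon or cluster-context requirement is imposed: matching is
deliberately context-free, and cross-referencing hits with cluster
predictions is downstream work. Coordinates are 0-based half-open on the
forward strand in machine output and BED export, 1-based inclusive in
the human-readable table (each file header states its convention).

## The synthetic generators

`generateNrpDatabase()` plants one cluster whose module predictions match
the query tag exactly (full-confidence prediction of each position's
first candidate) among decoys whose substrates are drawn from the
background frequencies — frequency-weighted decoys are *realistically
confusable*, where uniform decoys would overstate recovery. A
misprediction count forces the planted prediction at seeded positions to
a monomer outside the candidate set (match value exactly 0), emulating a
completely wrong substrate call. Under one seed, decoy $j$ is identical
across database sizes and the mispredicted position sets are nested
across counts, so recovery comparisons along those axes are exactly
paired — the monotonicities the tests assert are consequences of the
model, not sampling accidents.

`generateRippGenome()` plants one codon-realization of a peptide in
random background DNA on either strand and rejects backgrounds
containing any second occurrence of the peptide across the six frames,
making the planted locus the unique match by construction.

**What this does and does not show.** Passing the synthetic benchmarks
demonstrates the machinery: exact agreement with an exhaustive
enumerator, perfect recovery when predictions are perfect, graceful
monotone degradation as predictions are corrupted, and exact coordinate
arithmetic. Real substrate-specificity predictions are *partially*
wrong in correlated ways (under-represented taxa, rare monomers,
tandem duplications), real lineages are messier than the generator's,
and real genomes contain repeat families the uniform background cannot
produce — so absolute recovery numbers on synthetic data say nothing
about absolute performance on real strains; only the relative shapes
carry over.

The checked-in tests run at desk scale — 50 replicates per cell,
database sizes up to 100, 200 random clusters against the enumerator,
1000 planted-genome round trips — sizes chosen so the full suite stays
in the minutes range on one core while keeping every binomial
comparison well away from small-sample noise.

## Numerical and interface choices

* Natural logarithm throughout; the human-readable table rounds scores
  to 2 decimals, machine JSON keeps full precision.
* The database document is self-describing JSON with an embedded schema
  version (`pep2path-bgcdb/1`); Stachelhaus identities arriving as
  percents are normalized to fractions on load. Merging requires one
  alphabet to contain the other, deduplicates identical entries and
  refuses id collisions with differing content.
* Taxonomy is an ordered lineage list, not a rank-keyed map — real
  lineages vary in depth; rank keywords (domain, phylum, class, order,
  family, genus, species, strain) index into a declared rank order, and
  rank-free queries match anywhere in the lineage.
* Degenerate inputs: empty databases refuse to rank; a mass shift
  matching no table row is an error naming the shift; tag expansion
  beyond the cap is an error naming the product size; zero RiPP matches
  is a valid result.
* All randomness flows through locally seeded RNG scopes that restore
  the caller's RNG state, so identical inputs and seed give
  byte-identical outputs, including through the CLI.

## Known limitations

Scoring quality is bounded by the substrate-specificity predictions: for
taxa with sparse training data (fungi in particular) the Stachelhaus and
SVM channels are weaker and scores flatten towards the background. The
shipped background frequencies are a constructed stand-in. Gene-level
permutation cannot represent trans-acting or iteratively used modules.
The RiPP matcher deliberately knows nothing about precursor cleavage or
cluster context, so its hits are candidate loci, not validated
precursors.
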