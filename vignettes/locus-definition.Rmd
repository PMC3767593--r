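---
title: "Defining an XIST-like lncRNA locus: models, conventions and design choices"
author: "xistkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining an XIST-like lncRNA locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xistkit)
```

# The problem

XIST is the long non-coding RNA that triggers X-chromosome inactivation in
eutherian mammals. Defining such a gene on a freshly assembled genome is a
composite task: candidate regions are nominated by local alignment against
reference-species exons; the exon–intron structure is worked out by comparing
spliced cDNA amplicons with genomic DNA; scaffold N-gaps are filled from
bridging amplicons; exact transcript ends come from 5′/3′ RACE clone
sequences; internal tandem-repeat domains (the A-repeat and relatives) are
characterised by consensus monomers, fractional copy numbers and folded
secondary structure; the promoter's CpG sites are enumerated and their
clone-level bisulfite methylation is compared between the sexes; and the
resulting model is verified by mapping short RNA-seq reads.

`xistkit` implements each of these stages as a tested, reusable function, and
couples them to a synthetic-locus generator whose ground truth makes every
stage falsifiable without downloading any external data.

# The synthetic locus

`buildScaffold()` assembles the locus in a "gene-forward" frame (the
transcribed strand read 5′→3′: upstream flank, gene span, downstream flank)
and then reverse-complements it, because the default gene lies on the minus
strand with its TSS at the high scaffold coordinate — the descending-coordinate
geometry a real scaffold presents. Transcript position $t$ maps to scaffold
position $s = \mathrm{tss} - t + 1$ inside exons.

Two presets exist:

* `paperScaleGeneSpec()` — exons of 17,184 / 89 / 136 / 209 / 329 / 129 /
  7,139 bp and introns of 1,460 / 2,271 / 2,136 / 356 / 390 / 989 bp, i.e. a
  25,215-bp transcript over a 32,817-bp gene span, with the four repeat
  regions planted at transcript coordinates +327 (24-mer × 8), +2,723
  (6-mer × 23), +4,302 (96-mer × 91.7) and +24,059 (149-mer × 2), and a
  626-bp gap fill behind a 100-bp N placeholder in intron 2.
* `deskGeneSpec()` — a fast default with the five interior exons and all six
  introns at one tenth size. Exon 1 is kept at 3,200 bp, deliberately larger
  than a naive uniform shrink would make it: the promoter CpG window spans
  ±2 kb of the TSS, and in the real locus only the first (A-type) repeat
  region falls inside that window. A 1,7xx-bp exon 1 would drag every repeat
  region into the CpG window and force the CpG-exactness guarantee and the
  repeat planting into conflict; at 3,200 bp repeats 2–4 sit beyond +2,000,
  reproducing the real geometry.

Within the ±2-kb window the generator enforces an exact CpG layout: CG
dinucleotides occur at the 78 declared promoter offsets and nowhere else.
Sites follow the published counts — 13 dense sites between −284 and +53 and
54 between +285 and +1,727 (the 231-bp stretch between +54 and +284 is
site-free and splits the clusters), plus 11 sparse sites. Eight of the dense
sites are carried by the 24-mer repeat monomer (one CG per copy at monomer
position 11), which is why that monomer is fixed rather than random and why
its array is planted without divergence: random mutation would break the
exact CpG accounting. Promoter coordinates use the no-zero convention
throughout (+1 is the TSS base, −1 abuts it; intervals such as −6..+4 span
ten bases).

Repeat divergence defaults mirror the qualitative picture of the published
alignments: the 6-mer and 149-mer arrays are exact (the published 149-mer
copies are described as perfectly matched), the 96-mer array carries 10%
per-base substitution, and the 24-mer array is exact for the CpG reason
above. The fractional 91.7-copy array is planted as 91 full copies plus a
67-bp partial tail, so span/period recovers 91.7 after rounding.

Splice junctions are planted unambiguously: an exon never ends with the
acceptor's last base and never starts with the donor's first base. This makes
exon–intron inference unique and guarantees that spliced reads cannot run
into an intron with zero mismatches; junction-shift handling is still
exercised by constructed test cases.

What the generator does **not** emulate: sequencing errors (reads are
error-free with constant quality), PCR duplicates and amplification bias,
indels anywhere, bottom-strand bisulfite chemistry, partial or multi-isoform
transcription, and genome-scale background (flanks are uniform ACGT). A
green test suite therefore demonstrates correctness of the algorithms under
clean-data assumptions, not robustness to real sequencing noise.

# Candidate-region selection

`seedExtendAlign()` is a seed-and-extend local aligner: shared 11-mers are
clustered by diagonal and each cluster is rescored with a full affine-gap
Smith–Waterman over the clustered window, so every reported score is an exact
local-alignment score under the scoring scheme (match +2, mismatch −3, gap
open −5, gap extend −2; a gap of length $L$ costs $5 + 2L$). The published
candidate filter — alignment score above 300 with support from at least two
reference species — is implemented in `selectCandidates()` with a strict
inequality and with hit intervals merged by simple union (adjacent integer
ranges coalesce) before the species test. Scores from other tools are not
numerically comparable, so the 300 threshold should be read as calibrated
against this scheme; both the threshold and the species minimum are
arguments. The two-species rule is applied per merged region (the texts
leaves per-hit vs per-region open; per-region is the more permissive and is
flagged in the output by the listed supporting species).

# Exon–intron model assembly

`inferExons()` explains a spliced amplicon as ordered exact substrings of the
genomic region (greedy longest-prefix chaining with backtracking; introns
must be at least 20 bp). Exact matching is deliberate: the amplicons the
model is built from are Sanger-validated, and mismatch-tolerant spliced
alignment is out of scope. When identical bases flank a junction its
placement is ambiguous; the junction is shifted maximally 5′, except that a
shift yielding canonical GT/AG intron ends is preferred when one exists.
`validateSpliceSites()` reads donor/acceptor dinucleotides on the transcribed
strand; `fillGap()` replaces the single N-run with amplicon content anchored
by exact 30-bp flanks; `buildTranscript()` concatenates exons 5′→3′ and
records the transcript↔scaffold bijection; `summarizeModel()` emits the
per-feature first/last 8 bases and lengths with transcript and gene-span
totals.

# Transcript ends

`callTss()` maps each 5′ clone start onto the locus and reports every
distinct start with its support; calls 2 bp apart stay distinct (the
published −5 and −3 starts are separate sites). A clone anchor that lands
inside a tandem repeat matches several places; a placement only counts when
the entire clone matches there, which disambiguates every clone that extends
past the repeat.

`callTerminus()` trims poly-A tails (≥8 terminal A) at the last base still
matching the transcript, so genomic A-runs at the junction resolve in favour
of the longest genomic match — the standard RACE reading. A consequence worth
knowing: a terminus planted immediately upstream of a genomic A-run is
called at the end of that run, because the two positions produce identical
clones. The offset between expected and called terminus is reported both as
an inclusive position count (the published "10 bp downstream" spans positions
257,103…257,094 inclusive) and as the plain difference (9); the inclusive
value is primary because only it reproduces the printed number.
`findPolyASignal()` measures the signal distance as terminus position minus
signal end position (21 for the planted signal); the alternative
first-base convention is not used and the choice is recorded here.

# Tandem repeats and folding

`findTandemRepeats()` works in three stages. Candidate periods are voted by
the spacing histogram of repeated 8-mers. For each candidate period $p$ the
copy-vs-next-copy identity profile seeds rough stretches, delimited at base
resolution by a maximal-subarray pass over the lag-$p$ match vector with
log-likelihood weights ($\log(0.95/0.25)$ for a match, $\log(0.05/0.75)$ for
a mismatch — array content matches its period-neighbour with probability
near 0.95, flank content with 0.25). The copy phase is then enumerated and
each candidate explanation — full copies classified by gapless identity
against the per-column-majority consensus, plus at most one fractional tail
per end placed by the same log-likelihood walk — is scored by its total
log-likelihood, which penalises flank bases claimed as array content.
Fractional copy number is span/period rounded half-up to one decimal
(8,803/96 → 91.7).

Numerical floors, all chosen before testing and worth stating:

* regions shorter than 24 bp are not reported — random sequence is full of
  2–3-copy micro-repeats of tiny period, and the published regions are all
  ≥138 bp;
* fractional tails shorter than 6 bp are never counted (a random flank base
  continues the consensus with probability 1/4; a sub-hexamer "tail" is
  indistinguishable from chance), so for periods below 12 bp boundaries are
  copy-quantized and edge copies must reach the interior copies' identity;
* copy alignment is gapless — the published alignments show substitution-style
  divergence only, and indel-aware repeat alignment is out of scope;
* consensus ties resolve in fixed A<C<G<T order;
* overlapping detections are resolved largest-span-first after reducing each
  region to its primitive period (an array found at $2p$ re-refines at $p$),
  so a chance micro-repeat inside a long divergent array cannot displace it.

Boundary recovery on planted arrays is accurate to a couple of bases, which
keeps copy numbers within ±0.2 of truth; a residual ~0.3% of arrays (chance
flank continuation passing the 0.8-identity tail gate) exceed that — the
irreducible noise of the boundary problem, not a bug.

`probeMonomer()` is the query-monomer mode used for absence claims (such as
the murine C-repeat having no porcine counterpart): best gapless
sliding-window identity, absent below 0.7. `foldMonomer()` maximises
Watson–Crick plus GU pairs with minimum loop 3 by the classic
$O(n^3)$ recursion; traceback deterministically pairs the leftmost admissible
base with its leftmost optimal partner, and `countStemLoops()` counts
innermost pairs. Energy-model folding is intentionally not implemented — the
pair-maximisation recursion is the primitive under test, and its pair counts
are verified against exhaustive enumeration up to 14 nt.

# Methylation

`scanCpg()` lists CG positions in the ±2-kb window; `denseRegions()` chains
sites whose gap on the no-zero axis is at most 200 bp and reports chains of
at least 5 sites. The 200-bp default is what splits the published layout into
exactly its two dense clusters: the widest intra-cluster gap is well under
200 bp while the +54..+284 site-free stretch is 231 bp. `bisulfiteConvert()`
is a top-strand model: unmethylated cytosines (CpG or not) convert C→T with
the given rate; methylated-CpG cytosines are protected. `callMethylation()`
places clones by exact matching in the C/T-collapsed space (the only
degeneracy conversion introduces), calls C→methylated / T→unmethylated at
each covered site, and excludes clones whose non-CpG cytosine conversion is
below 0.95 — a conventional quality floor; the source text states no rule.
Clone counts per amplicon region default to 10, a free choice (the published
figure shows per-clone rows but no counts).

`summarizeMethylation()` rounds half-up (two decimals for percentages, one
for mean sites per clone) and reports both the pooled-call aggregate and the
clone-mean aggregate; the two coincide when every clone covers every site,
and the published aggregates do not distinguish them. Note that a clone mean
of 64.5 sites of 67 gives 96.27% under half-up rounding where 96.26% is
printed — the printed figure appears truncated, and comparisons against it
carry a ±0.02 band for that reason.

One statistical point about the recovery tests: with per-site binomial
sampling at $n = 200$ clones, requiring every one of the 67 sites (134
site×sex draws) to fall within 3 SEs of its planted probability would fail
about one run in three under the model's own assumptions
($0.997^{134} \approx 0.67$). The suite therefore checks each site against
the family-wise equivalent bound (the Bonferroni-adjusted quantile at the
same 0.0027 family level, ≈4.3 SEs) and the pooled estimate against a strict
3 SEs of its model expectation $p + (1-p)(1-\text{conversion})$; exact
call-vs-truth agreement at full conversion is asserted separately.

# Coverage

`mapReads()` places each read at its true best hit — minimal Hamming distance
over every ungapped offset on both strands, ties leftmost then forward
strand — with no heuristic seeding, and `coverageTrack()` normalises depth by
total aligned reads. Paired reads are treated as independent single-end
placements: coverage, not structural inference, is the goal.
`expressionCheck()` reports the exonic fraction of aligned bases, the
coverage start relative to the TSS-call window, terminal coverage, flank
zero-depth flags, and positions exceeding five times the exonic median —
the repeat-ambiguity peaks a best-hit mapper produces over internal repeats.
Error-free reads are mapped at zero mismatches in the sex-specificity
checks, which makes the female exonic fraction exactly 1.0 and male
transcript alignments exactly 0.

# Problem sizes

The routine test suite runs the desk-scale locus (8.2-kb scaffold, 4.8-kb
transcript) everywhere, with the full-size 35.5-kb locus built only for the
table-arithmetic and repeat-coordinate checks; read simulations use 300–800
pairs of 90-bp reads, bisulfite recovery 120–200 clones per region, and the
property sweeps 15–50 seeds per case. These sizes were chosen so the whole
suite completes in about a minute while every assertion retains its
statistical meaning.

# Known limitations

Exact-match assembly (no tolerance for amplicon sequencing errors); gapless
repeat copies; IUPAC-only motif matching (no weight matrices — the published
motif evidence is consensus-string matching); top-strand bisulfite only; no
E-value model for alignment hits; single-isoform transcripts; and the
terminus convention above for ends abutting genomic A-runs.
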