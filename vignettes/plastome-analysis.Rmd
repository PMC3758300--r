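---
title: "Plastome structure, codon usage, repeats, RNA editing and character mapping with plastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure, codon usage, repeats, RNA editing and character mapping with plastkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastkit)
```

`plastkit` reimplements the computations of a comparative chloroplast
genome study as a tested pipeline.  This vignette is the package's own
account of the underlying methods: the models and their assumptions, the
parameters that matter, the numerical conventions, and what the synthetic
generators do and do not emulate.

## The quadripartite model

A plastome is modelled as a circular DNA string over \{A,C,G,T,N\} carrying
an inverted-repeat pair: the longest pair of non-overlapping intervals
(X, Y) with seq(Y) equal to the reverse complement of seq(X).  Exact
identity is asserted between the copies — the genome-as-assembled
semantics, in which assemblers collapse the two IR copies so they are
literally identical.  A mismatch-tolerant mode is deliberately out of
scope, and an N never matches an N, so ambiguity inside a claimed IR
breaks it.

`detect_inverted_repeat_pair()` anchors matching 25-mers between the
genome and its reverse complement; matches fall on diagonals, and maximal
runs along a diagonal are maximal common substrings.  The default
`min_length = 1000` bp reflects the biology: plastid IRs are tens of kb,
and a high floor removes the fold-back palindromes and short inverted
microrepeats every genome contains.  Returning `NULL` (the "no-IR"
signal) is distinct from returning a zero-length interval — some lineages
(e.g. one clade of legumes) genuinely lack an IR copy.  On circular
genomes, a second pass on a half-rotation catches pairs spanning the
origin; a single IR pair cannot span both cut points at once.

`partition_quadripartite()` labels the longer single-copy segment LSC and
the shorter SSC, and reports the partition in a canonical rotation with
the LSC start at coordinate 0, giving the order LSC, IRb, SSC, IRa around
the circle.  On a tie between the segments, the segment following the
first IR copy is declared SSC — an arbitrary but deterministic rule that
is stated rather than hidden.  Published genome records do not follow one
strand/rotation convention, so the canonical frame is the package's own;
the `offset` field maps input coordinates into it.  All interval
arithmetic is 0-based half-open internally, converted to the 1-based
inclusive conventions of annotation TSV/GenBank files only at the I/O
boundary — junction distance arithmetic is the main beneficiary.

Junction profiles report, per gene, the signed distance from the gene end
nearest to its nearest junction: non-negative for a gap, negative for the
overhang when the gene straddles the junction (the smaller of the two
overhangs).  This is the quantity used in cross-species IR boundary
figures, where e.g. a duplicated *rps19* truncated by IR contraction shows
up as a negative distance at the IRa/LSC junction.

## Codon usage and RSCU

Codons are extracted from all exons of protein-coding genes — pseudogenes
and RNA genes are skipped — spliced in transcription order and
reverse-complemented for minus-strand genes.  A CDS length that is not a
multiple of 3 warns and drops the remainder; codons containing N are
dropped with a warning; internal stop codons warn but do not abort,
because plastid annotations legitimately contain ACG and GUG initiator
codons (ACG start codons are restored to AUG by C-to-U editing at the
transcript level) and counting operates on the genomic sequence as
annotated.

RSCU follows the standard definition: count × family size / family total
under the standard genetic code (family sizes 1, 2, 3, 4, 6; stop codons
excluded).  Families with zero totals give NA, not 0.  The packaged
reference codon-usage table preserves its published RSCU column verbatim
as `rscu_printed`: for two-fold families that column equals the standard
formula, but for 3-, 4- and 6-fold families it is consistent with a
factor-2 formula (count × 2 / family total), which is not the community
meaning of RSCU.  `rscu()` therefore implements the standard formula
only, and tests compare against the printed column solely on two-fold
families plus re-derived standard values elsewhere (e.g. UUA at
785 × 6 / 2624 = 1.79).  Reported values are rounded half away from zero
to 2 decimals (`round_half_up()`), matching table formatting; internal
values stay at full precision.

## Exact repeat families

The repeat finder reports what published plastome repeat tables actually
contain: families of a unit longer than 10 bp (default `min_period = 11`,
which also suppresses homopolymer and dinucleotide microsatellites),
period at most 500 bp, 100% identity between copies, and at least two
same-strand copies or an inverted partner.  The alignment-score settings
of the original discovery tool are intentionally not reproduced: they
imply a minimum repeat length contradicted by the 12-bp families the
tables list, so the criteria the results reflect take precedence.

Mechanically, maximal repeated pairs come from k-mer-anchored diagonal
runs (k = `min_period`).  A pair whose shift is at most its match length
is a tandem array — the period is the shift, the copy count
floor(L/p) + 1 — while a larger shift is a direct pair whose unit is the
whole match.  All occurrences of one identical unit form a family; a
family is typed T if any adjacent copies sit exactly one period apart
(published tables label a family tandem even when a third copy lies
further away), else D.  An inverted match is reported as a single-copy
partner record carrying the plus-strand unit of its primary family,
mirroring the published convention.

Two suppression rules keep the output at the level of the published
tables.  A family whose unit is an exact concatenation power of a shorter
reported unit over the same positions is dropped in favour of the
primitive period.  A family whose unit is a substring of a longer
reported family and whose occurrences all lie inside that family's copies
is dropped as a trivial internal repeat — but kept when any occurrence
pokes outside, which is exactly how a 19-bp tandem nested at a 30-bp
direct repeat's locus earns its own table row.  The package's fixture
reconstruction pins this down: the printed coordinates of that nested
tandem imply a unique 3-bp spacer ("TAC") between the two 30-bp copies,
and detection on the reconstructed locus reproduces both rows without the
nested one being planted.

Coordinates in reports are 1-based to mirror the published tables.  At
genome scale, the IR pair itself is an inverted repeat of ~26 kb; the
`max_period` filter keeps it out of repeat reports.

## C-to-U editing prediction

The editing predictor scores every genomic C on the coding strand.  The
candidate's edited codon substitutes T at that position; the score is

score = matches(edited residue) / (matches(edited) + matches(unedited))

over the reference panel column for that codon, with gaps and
non-matching residues excluded from the denominator, 0 when the
denominator is empty, and 0 for silent or stop-introducing candidates.
Sites scoring at or above the cutoff (default 0.8, inclusive — the
boundary case 8/10 is called) are predicted.  The scoring function is the
package's own: the published predictor's internals and 35-gene reference
panel are proprietary, so its absolute site count is explicitly not a
reproduction target, and a gene can be unpredicted either because its
score fell short or because no panel exists for it.

Summaries over observed editing tables count sites whose RT-PCR state is
in `confirmed_states`; partial editing ("+/−", both edited and unedited
transcripts present) counts as confirmed by default because only then do
the published per-position tallies reproduce from the table rows — the
parameter makes that choice explicit and overridable.  Codon position and
amino-acid change are taken from the recorded fields rather than
re-derived, since a few published rows are internally inconsistent with
their codon strings; `validate_editing_rows()` flags such rows without
altering counts.  Hydropathy transitions use a fixed two-class table —
hydrophobic \{A,V,L,I,P,F,M,W,Y,C\}, hydrophilic \{R,N,D,E,Q,H,K,S,T,G\} —
the minimal assignment consistent with every published classification the
summaries rest on (tyrosine hydrophobic; serine, threonine, histidine,
glycine hydrophilic).

## Parsimony character mapping

Gene duplication, pseudogenization and loss events are mapped onto a
fixed rooted phylogeny under equal-cost parsimony.  The implementation is
a unit-cost Sankoff dynamic programme — cost(node, state) = sum over
children of min(cost(child, s′) + [s ≠ s′]) — which is exact for
polytomies, multistate alphabets and a constrained root, unlike the
textbook two-pass Fitch sets.  `count_independent_origins()` augments the
table with a second objective, minimized lexicographically after cost:
the number of edges entering the derived state.  The root defaults to the
ancestral (absent) state for origin counting, matching the directional
narrative gain → duplication → pseudogenization → loss.  Unknown leaf
states ("?"/NA) are free.

The packaged 25-taxon tree is a transcription of a published monocot
phylogeny, not an inference: the monocot backbone (Acorus, then
Colocasia, then Cymbidium, then commelinids with Arecales sister to
Dasypogonaceae and Poales sister to Zingiberales + Commelinales), palm
relationships with coconut sister to oil palm, and magnoliids with
Chloranthus sister to ((Drimys, Piper), Magnolia).  The placement of the
two eudicots (Ceratophyllum, Nandina) as a clade sister to
monocots + magnoliids is underdetermined by the source text; it does not
affect either mapped character, whose derived leaves are isolated or
confined to clades elsewhere, but it is a convention of this fixture, not
a claim.  Both headline characters — the *ndhF*/ψ*ycf1* overlap and the
*rps19* pseudogenization — require three independent origins under these
states.

## Synthetic data: what it emulates, what it does not

All generators are pure functions of their arguments plus an integer
seed, and byte-identical across runs — the determinism is itself tested.

`make_quadripartite_genome()` assembles LSC + IRb + SSC + revcomp(IRb)
from random sequence at the AT-rich plastid composition (GC 0.374, the
coconut genome-wide value).  Its defaults are the coconut region lengths
(LSC 84,230, SSC 17,391, IR 2 × 26,555 = 53,110; genome 154,731 bp).
Single-copy regions are verified repeat-free at the detection scale: a
31-mer census across both strands must show exactly the duplications the
IR explains, and the four region-boundary bases are resampled so the
planted IR cannot be extended by even one base (a 1-bp extension would
shift every recovered junction).  Real plastomes are not random sequence
— they carry genes, microsatellites and the repeat families above — so
passing recovery tests on these genomes demonstrates correctness of the
structural algorithms, not robustness to biological repeat content; the
repeat-fixture generator covers that separately.

`make_repeat_fixture()` lays out requested repeat records with stated
inter-copy gaps inside random flanks and spacers.  Because planted units
are internally periodic and the background AT-rich, chance continuations
are common; the generator therefore (a) breaks the extension frontier of
every planted copy pair (and inverted partner, under complementarity) by
resampling the first random character that continues a match, and (b)
repairs any duplicated 11-mer not explained by a single record group by
resampling one of its random characters, iterating to a fixed point.
Records whose fixed characters genuinely collide — e.g. two published
rows that share a 10-mer through a coordinate-implied spacer and cannot
coexist in a compact fixture at the 11-bp uniqueness floor, although they
are tens of kb apart in the real genome — are refused rather than
silently bent, and the test suite splits such rows across fixtures.

`make_homolog_panel()` plants edits at stated support fractions; the
achieved support is floor(support × panel size)/panel size so a fraction
below the calling cutoff can never round up across it.  Background
columns agree with the unedited translation except for an optional
sub-cutoff dissent fraction.  Planted codons carry exactly one C, so
recovery is unambiguous; real codons with several C's are evaluated per
position by the predictor but are not planted.

## Numerical conventions and degenerate inputs

* Rounding for display is half-away-from-zero at 2 decimals; all
  computation is at full precision and rounds only at serialization.
* Detection ties (equal-length IR candidates, repeat output order) break
  deterministically by start coordinate, then period descending.
* Zero-length GC windows, empty FASTA files, exons outside the genome,
  non-triplet codon tokens, unknown feature kinds and unknown gene names
  raise specific errors; an empty annotation list or an empty editing
  table is a valid input with an empty/zero result.
* The counting convention for "total genes" in published comparisons is
  inconsistent across sources (IR duplicates and pseudogene copies are
  variously included); the package reports raw per-record counts and the
  comparison fixture preserves published values verbatim, flagged rather
  than arbitrated.

## Test problem sizes

The suite exercises: oracle equivalence of the repeat finder against an
O(n²) diagonal-scan oracle on 50+ seeded sequences of 200–500 bp (with a
deliberately low-complexity base composition to raise repeat density);
exhaustive-labeling parsimony oracles on random trees of up to 8 leaves,
with polytomies and three-state characters; planted-edit recovery on
CDSs of 100–200 codons and panels of 10 references; and full-scale
quadripartite recovery at the coconut dimensions (154,731 bp), which runs
in a few seconds.  These sizes keep the default test run fast while the
properties they check are size-independent.

## Known limitations

* Exact-identity repeats and IRs only; no mismatch-tolerant detection.
* The editing predictor's absolute site counts are panel-dependent;
  only planted-truth recovery and the summary statistics of observed
  tables are validated quantities.
* Annotation handling reads features as given: no gene prediction, no
  tRNA structure validation, no re-annotation.
* The comparison report consumes per-species values; it does not fetch
  or recompute other species' genomes.
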