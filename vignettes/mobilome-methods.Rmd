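---
title: "Methods: detecting and classifying mobile genetic elements with mgescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying mobile genetic elements with mgescout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgescout)
```

`mgescout` characterizes candidate mobile genetic elements (MGEs) in
assembled bacterial genomes: plasmid topology, repeat architecture, ESX
(type VII secretion system) loci, a feature-matrix classification, and
shared-segment comparison between elements. This vignette records the
models and procedures behind each stage, the tunable parameters and why
their defaults are what they are, and the limits of what the synthetic
test suite can demonstrate.

## Inputs and coordinate conventions

A replicon is a contig sequence over `{A,C,G,T,N}` plus an ordered feature
table (`AnnotatedReplicon`). Coordinates are 1-based inclusive everywhere —
inputs, outputs, logs — matching GenBank/GFF3 convention; any half-open
arithmetic is internal. `N` is legal in sequence but never matches
anything in repeat, overlap, or segment detection: draft assemblies contain
gaps, and a gap should never manufacture evidence.

Annotation arrives as GFF3 or a documented TSV dialect (`contig, start,
end, strand, ftype, product, domain_tags`, tags semicolon-joined,
versioned header comment). Domain *tags* — a controlled vocabulary
(`mge_tag_vocabulary()`) covering replication (RepA, DnaB-like helicase,
DNA polymerase I), conjugation (relaxase, VirD4, VirB4, TcpC), integration
(integrase, DDE/IS transposase), stability (toxin/antitoxin), tRNA, and
the six ESX core components — are the interface between upstream
annotation and every downstream decision. Profile-HMM searching itself is
out of scope (HMMER does it well); `assign_domain_tags()` bridges the
common case where only Prokka-style product strings are available, by a
regex synonym table. One deliberate rule there: products carrying a DDE
motif or an insertion-sequence name are tagged `transposase`, not
`integrase`, so that DDE-type integrase/transposase/recombinases score in
the transposase row of the feature matrix.

Unknown tags are rejected at load with a warning rather than silently
dropped: a typo in an annotation pipeline should be visible, not a silent
false negative.

## The repeat finder

The engine behind TIR detection, direct-repeat boundary calls, and the
repeat-architecture report is a maximal-pair finder over ungapped
(Hamming) identity. A repeat pair is two equal-length, non-overlapping
arms (`arm2_start > arm1_end`); for inverted orientation arm2 matches the
reverse complement of arm1. A pair is reported when identity ≥
`min_identity`, length ≥ `min_len`, and it is *one-step maximal*:
extending both arms by one base on either side — onto a mismatch, past a
sequence boundary, or into arm overlap — would push identity below the
threshold.

Gapped alignment is deliberately absent. The repeats this tool exists for
(terminal inverted repeats, integration-scar direct repeats) are 99–100%
identity, where an ungapped model is exact, reproducible, and trivially
explainable; an affine-gap model would add parameters without adding
evidence.

Implementation: on each diagonal (direct) or antidiagonal (inverted) the
match structure is a 0/1 vector, and with the prefix statistic
$G(t) = 100\,\mathrm{matches}(t) - p\,t$ a window passes the threshold iff
$G(b{+}1) \ge G(a)$ and is maximal iff additionally
$G(b{+}1) < G(a) + p$. Enumeration is therefore a band query over sorted
$G$ values — linearithmic per diagonal. Sequences up to 4 kb are scanned
over every diagonal; larger ones only over diagonals containing an exact
k-mer seed, with the seed length capped by what the thresholds guarantee
(a window of length `min_len` at identity `p` must contain an exact run of
$\lceil (L-e)/(e{+}1) \rceil$ with $e = \lfloor (1-p)L \rfloor$ mismatches,
so nothing reportable can be missed). Overlapping reports of the same
repeat are collapsed to the longest, then leftmost, representative. The
test suite pins all of this to a brute-force oracle that enumerates
windows straight from the definition.

Two parameter mappings worth recording:

- `min_len` defaults to 100 bp for genome-wide scans — the conventional
  scan-window scale for this kind of survey — and 50 bp for TIR scans, so
  short termini are not missed. Both are configuration, not constants.
- One consequence of the maximality semantics: at thresholds below 100%,
  a *perfect* planted repeat is reported as a slightly longer window
  whenever the identity budget allows absorbing flanking near-matches.
  That is the correct answer to the question asked. Exact-length recovery
  of perfect repeats is therefore always checked at `min_identity = 100`,
  and the synthetic generator additionally breaks flanking bases so that
  planted arms are recovered at exactly their planted coordinates.

`find_terminal_inverted_repeats()` keeps the longest inverted pair whose
arms start/end within `max_offset` (default 100 bp) of the two termini —
assembly ends are ragged, and a hard "position 1" requirement would be
brittle. TIR scans default to `min_identity = 95` for sensitivity to
degraded termini; length-exact assertions use 100.

## Topology calls

Three evidence channels, mirroring how plasmid circularity is established
from assemblies:

1. **Terminal redundancy** — the largest `L` in
   `[min_overlap, max_overlap]` (defaults 20, 2000) with
   `prefix(L) == suffix(L)` exactly. Assembler-duplicated termini are
   exact copies; tolerating mismatches would need an alignment model with
   no corresponding signal.
2. **Spanning read pairs** — mates within `end_window` (default 500 bp) of
   opposite ends, pointing outward (`-` on the left end, `+` on the
   right): the footprint an insert spanning the circular junction leaves
   after linearization. The threshold is 3 pairs — liberal, because the
   generator and desk-scale datasets carry tens of pairs, and every value
   is exposed in `mge_params()`.
3. **TIR** — supports a *linear* call.

Circular evidence wins over a TIR (physical read-pair/overlap evidence
outranks a sequence motif, and inverted repeats do occur in circular
molecules); the conflict is recorded in `evidence_notes` rather than
hidden. No channel firing yields `unresolved`, never a guess.

## ESX locus calling and signature typing

Core-component genes (EccA, EccB, EccC, EccD, EccE, MycP — identified by
tags, not by sequence) are clustered by single linkage along the replicon:
consecutive core genes with an intergenic gap ≤ `max_gap` join one
cluster; clusters with ≥ `min_core = 4` members become loci. `max_gap`
defaults to 6 kb, sized from the span of described mycobacterial loci
(core genes sit within a few kb of each other); "close to each other" is
the field's phrasing, and the number is our recorded operationalization.
An unclustered EccA within `eccA_reach = 20` kb downstream (in the
reading direction of the locus's majority strand, which keeps the call
strand-symmetric) is attached as a distal member — mobile-element ESX loci place eccA roughly 17 kb from
the core cluster — and the gene-order signature marks that jump with
`-//-`. Duplicated core genes are kept as distinct tokens; that is what
distinguishes ESX-4-bis (two eccD) from its relatives.

Typing is signature matching, not phylogenetics: the locus's token
sequence (gap markers dropped) is compared to each reference signature by
Levenshtein distance over gene-name tokens, in both reading directions,
because the genomic orientation of a mobile element is arbitrary. Smallest
distance wins; ties or distance > `type_max_dist` (default 1) give
`untyped` — a deliberate bias toward honesty over coverage. The bundled
table (`esx_reference_signatures()`) carries the two mobile-element orders
(ESX-4-bis as in ICEMyc226/*M. mageritense*; ESX-2-like as in
pCBMA213_2/pMKMS01) and the canonical chromosomal ESX-1 (split
eccCa/eccCb), ESX-3 and ESX-4 (no eccA/eccE) layouts, each with a
provenance column; users extend it by rbinding rows. A maximum-likelihood
protein phylogeny would type loci the reference table cannot, but it drags
in alignment, masking and tree inference — machinery that belongs to
dedicated tools, and whose output is not reproducible from a seed.

## The feature matrix and classification cascade

`build_profile()` reduces a replicon to the presence/absence vector used
in mobilome summary tables: each flag is true when ≥ 1 feature carries the
corresponding tag; `t7ss` is true exactly when ESX loci were called;
`toxin_antitoxin` requires a toxin and an antitoxin tag within one
intervening gene — explicitly a keyword/adjacency heuristic, weaker than
dedicated TA predictors, and sufficient only for presence/absence.

The cascade (first match wins):

1. `putative_ICE`: relaxase ∧ (virB4 ∨ virD4) ∧ (integrase ∨
   DDE-transposase) ∧ ¬repA. A T4SS-mediated ICE carries its conjugation
   module and an integration enzyme but relies on the host replicon, so
   repA vetoes the call.
2. `conjugative_plasmid`: (repA ∨ helicase) ∧ relaxase ∧ (virB4 ∨ virD4).
   A DnaB-like replicative helicase is accepted as replication evidence
   because repA-less linear plasmids replicate by exactly that route.
3. `cryptic_plasmid`: (repA ∨ helicase) ∧ ¬relaxase. Note this bucket
   includes replicons carrying T4SS fragments without a relaxase — a
   megaplasmid with virB4 but no relaxase lands here, and the report
   still shows the virB4 flag, so the ambiguity is surfaced rather than
   resolved by fiat.
4. `unclassified` otherwise.

The field draws no sharp quantitative line between an ICE and an
integrated conjugative-plasmid remnant; this cascade is a recorded,
testable operationalization, pure in the flag vector (feature order can
never change a call).

`delimit_integrated_regions()` turns high-identity (≥ 99%) direct-repeat
pairs into candidate integrated regions when the inter-arm region contains
coding genes, recording the nearest DDE/IS-tagged feature within
`max_adjacency = 1` kb of either arm ("adjacent" is unquantified in
descriptions of such architectures; 1 kb is our recorded choice). Regions
are bounded by the arms' inner edges and sorted outermost first, so nested
pairs read naturally.

## Shared-segment comparison

`find_shared_segments()` is anchor-and-chain: exact 21-mer anchors (both
strands), merged into exact blocks, chained collinearly when gaps in both
sequences stay ≤ 2 kb, chains resolved greedily by anchored length with
leftmost ties, then extended outward by ungapped X-drop (+1 match, −2
mismatch, drop 20). Identity is computed over the chained span —
base-by-base when the chain sits on one diagonal, piecewise with
diagonal-shift gaps counted as unaligned otherwise. Defaults (`k = 21`,
`min_segment = 1000`, `max_gap = 2000`) are sized for ~90%-identity
mycobacterial homology: at 10% divergence roughly one 21-mer in nine
survives, far denser than the 2 kb chaining gap. The same operator doubles
as a reference-plasmid screen when B is a user-supplied reference FASTA.
`summarize_sharing()` reports per-element coverage (B-side overlaps merged
first) and length-weighted identity.

## The synthetic generator and what passing tests show

The generator plants architectures with exact, serialized truth
(`SyntheticTruth` YAML beside every fixture): TIRs at the termini
(perfect, or degraded by an exact number of interior substitutions),
duplicated termini with outward-oriented spanning links (plus a binomial
mispairing fraction for noise studies), direct-repeat pairs around a
cargo, ESX clusters in any requested token order with the distal-eccA
jump, backbone genes realizing any flag set — including contradictory
ones, generated as asked with the request recorded, because classifier
tests need contradictions too.

Defaults are the study conditions the package is demonstrated on: the
21,616 bp linear replicon with a 489 bp perfect TIR; the 101 bp / 99%
degraded-repeat case (realized as exactly one interior substitution); the
160,489 bp circular replicon with a 77 bp duplicated terminus and 30
spanning pairs; the 388,440 bp ICE with 167 bp cargo-flanking and 648 bp
outer direct repeats, a 40 kb ESX cargo, both mobile-element ESX
signatures, and an IS-tagged transposase 200 bp beyond the downstream arm.
Unit tests run the same architectures at reduced lengths (4–130 kb) so the
suite completes in minutes; the acceptance script uses the full scales.

Randomness is R's Mersenne-Twister, pinned explicitly (`set.seed(seed,
kind = "Mersenne-Twister", sample.kind = "Rejection")`), so fixtures are
byte-reproducible from the seed alone. Backgrounds are rejection-sampled
to contain no unplanted ≥ 50 bp perfect repeat and to sit within one point
of the target GC; planted arms get mismatching flanking bases so their
recovered coordinates are exact.

What this does **not** show: real assemblies have repeat families, mobile
elements in multiple copies, ragged and gap-containing contig ends, and
annotation errors. The generator's backgrounds are i.i.d. random sequence
— much cleaner than a genome. Passing the planted-truth suite demonstrates
that the algorithms do what their definitions say under known conditions;
it does not bound false-positive rates on real mycobacterial assemblies.
The accession-validation path exists for exactly that reason:
`validate_reference_elements(dir)` recomputes lengths, GC, CDS/tRNA
counts, TIR lengths (145 and 489 bp), the 167/648 bp direct repeats, and
the plasmid-vs-ICE sharing summary (≈70% coverage at ≈90% identity,
checked to ±5 points since the deposited characterization reports both
with "~") from local copies of GenBank MF600313.1, KY349138.1, MN587875
and MN587876. The records are not redistributed; download each accession's
nucleotide FASTA into a directory (plus optional feature tables) and point
the function at it.

## Numerical and degenerate-input choices

- Identity comparisons use `matches × 100 ≥ p × len − 10⁻⁷` so integer
  thresholds compare exactly in floating point.
- A sequence shorter than `2·min_len` yields an empty repeat set, not an
  error; an all-`N` or empty sequence makes GC undefined and is a distinct
  error, never 0.
- End-overlap length is capped at half the sequence; the degenerate
  "whole sequence is its own overlap" is meaningless.
- Ties everywhere break deterministically (length desc, then leftmost):
  two runs on one machine, or two machines, give identical reports.
- Repeat dedup drops a pair only when *both* arms overlap both arms of a
  kept pair — distinct repeats sharing one arm survive.

## Known limitations

- Ungapped arms: a TIR interrupted by an indel is reported as two shorter
  pairs, not one gapped one.
- Seeded scans below ~99% identity on megabase inputs examine many
  diagonals; the intended regime for low thresholds is selected regions or
  desk-scale replicons.
- ESX typing is bounded by the reference table; novel locus orders come
  out `untyped` by design.
- The TA flag is a heuristic; treat it as a pointer, not a call.
- Read-pair evidence arrives as a position table, not SAM/BAM — producing
  that table from a mapper is a one-liner left to the user.
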