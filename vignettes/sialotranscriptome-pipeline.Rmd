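---
title: "Assembling and annotating a deep salivary-gland transcriptome"
author: "SialoKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and annotating a deep salivary-gland transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SialoKit)
```

## The problem

Blood-feeding arthropods inject saliva whose proteins antagonize host
hemostasis and immunity.  Surveying a salivary-gland transcriptome
(a *sialotranscriptome*) by deep pyrosequencing produces on the order
of a million short reads (~344 nt) that must be clusterized and
assembled into contigs, translated and matched against annotated
protein references, repaired where sequencing indels broke the reading
frame, classified into secreted / housekeeping / unknown /
transposable-element products, organized into multigene families, and
examined phylogenetically for evidence of gene-family expansion.
SialoKit implements that pipeline as composable, tested stages, plus a
synthetic read generator with complete ground-truth bookkeeping so
every stage can be validated without any external data.

## Clusterization and assembly

Reads are grouped by *shared exact words*: two sequences belong
together when they are connected by a chain of pairs sharing at least
one exact word of the current word size, on either strand.  Each group
is assembled greedily (longest qualifying overlap first, either
orientation) with a quality-weighted per-column consensus, and the
consensuses — with per-column qualities derived from the summed
evidence, capped at phred 60 — feed the next round at a smaller word
size.  The default schedule is 200, 134, 90, 60, 40, 40.  A "match" is
an exact shared word, not a full gapped extension: word sharing is the
grouping trigger the decreasing-word-size strategy exploits, and
overlap quality is enforced later by the assembler's identity gate
(default: overlap of at least 40 nt at 90% identity, tolerant of
typical pyrosequencing error).  The per-query match cap (default 1000)
mirrors the usual search-tool limit but cannot change the partition,
which is defined as a transitive closure.

Numerical conventions in the consensus caller: the base (or gap) with
the highest summed phred wins a column; equal sums go to the
alphabetically first base, and gaps lose ties to bases; columns with no
evidence call N; gap-winning columns are removed.  Ties between
candidate merges are broken by overlap identity and then by the
lexicographically smallest member-id pair, which makes assembly
deterministic for a fixed input regardless of processing order.  Each
round re-seeds the assembler from consensus plus derived quality, as if
a fresh FASTA/qual pair were handed over, so read membership
accounting — every input read in exactly one final contig — is exact by
construction.  The greedy merge is a deliberate simplification of a
full overlap-layout-consensus assembler; it handles the dominant 454
error mode (homopolymer indels are outvoted by coverage) but makes no
attempt at repeat resolution.

## Coding-sequence extraction and frameshift repair

Filtered contigs (by default longer than 149 nt with at least 5 reads)
are translated in six frames and searched against reference proteins
with ungapped local alignments (BLOSUM62).  Gap penalties are set
prohibitively high on purpose: a sequencing indel then splits the
homology into two HSPs in *different frames*, which is exactly the
signal the repair consumes.  A per-subject chain (same strand, subject
and query coordinates increasing, query gaps of at most 90 nt so
repairs stay local) must cover at least half of the subject protein.
The CDS spans the chain, extended upstream to the most distant in-frame
methionine reachable without crossing a stop codon (within 300 codons)
and downstream to the first stop.  Between adjacent HSPs whose frames
differ, the bridging nucleotides are replaced by N's and the bridge
length is adjusted by +1 or −1 — whichever is the smaller edit that
restores the reading frame — and each frame change counts as one
repair.  N-containing codons translate to X, so a repair is visible in
the protein as a short X block.

The significance measure attached to each hit is a Karlin–Altschul
style surrogate, `E = K·m·n·exp(−λ·S)` with the conventional ungapped
BLOSUM62 constants (K = 0.041, λ = 0.267).  Only its ordering and
thresholding behaviour matter to the pipeline; it is not calibrated to
any particular search engine's statistics.  Two refinements keep
near-terminal homology from being lost.  First, *all* local segments
at or above the score threshold are reported per frame — found by
masking each reported span and re-searching — so a contig with two
indels that cancel back into the original frame still presents both
same-frame fragments to the chainer instead of only the
better-scoring one.  Second, when the best chain leaves an uncovered
subject prefix or suffix that the query still encodes, that region is
re-searched in isolation with significance judged against its own
(tiny) search space: an indel within a dozen codons of the coding
start cuts off a fragment far too short to reach the genome-wide
threshold, yet unambiguous in the targeted re-search.  This terminal
rescue is what lets start-proximal features — above all signal
peptides — survive repair instead of being silently truncated.

## Classification

Each CDS is classified by deterministic rule precedence:
(1) contaminant hit (rRNA/mitochondrial word match) ⇒ housekeeping
"rRNA-mito"; (2) transposon keyword within its e-value bound ⇒
transposable element; (3) signal peptide with at most one membrane
helix ⇒ secreted, with the subcategory of the best secreted-family
keyword, or "putative secreted, unknown family" when nothing
informative (default: e ≤ 1e−5) matched at all; (4) any housekeeping
keyword ⇒ housekeeping; (5) otherwise unknown.  Because precedence is
rule-based rather than order-based, permuting the databases never
changes an outcome, and the returned rationale lists every rule fired
or skipped.  The shipped vocabulary (~30 secreted subcategories:
Kunitz, TIL, thyropin, cystatin, serpin, Kazal, carboxypeptidase
inhibitor, PEBP, metalloprotease, serine protease, legumain,
endonuclease, 5′-nucleotidase/apyrase, lipase/esterase, glycosidase,
sulfatase, lipocalin, antigen-5/CRISP, prokineticin, serum amyloid,
mucin, antimicrobial, glycine-rich/cement, GGY, ixodegrin, disintegrin,
Salp15-like, basic-tail/18.3-kDa, 23-kDa, 8.9-kDa, ixostatin,
one-of-each, evasin, DAP-36, 13-kDa) is an editable table; possibly
lysosomal secreted enzymes are kept in the secreted class, matching the
usual accounting of such surveys.

The sequence signals use documented built-in heuristics rather than
external predictor servers, and externally computed verdicts can be
substituted through plain tab-separated files:

* **Signal peptide** — within residues 1–35, a window of ≥ 8 residues
  with mean Kyte–Doolittle hydropathy ≥ 1.6 followed within 6 residues
  by a small residue (A, G, S, C, T), which is reported as the cleavage
  position.  All windows are enumerated; the first qualifying
  (start, end, cleavage) in scan order wins, so a strongly hydrophobic
  core cannot mask a nearby cleavage site.
* **Membrane helices** — disjoint windows of ≥ 19 residues with mean
  hydropathy ≥ 1.6 after the cleavage site.
* **O-glycosylation** — S/T residues whose surrounding 11-mer holds ≥ 5
  of S/T/P, the low-complexity density characteristic of mucins.
* **Furin sites** — the R-X-[KR]-R motif, overlapping matches included.

## Families, gene counts, motifs

Deduced proteins are clusterized progressively from 25% to 99%
identity over at least 50% of the length of the longer sequence.
Similarity is implemented as identity fraction from a free-end-gap
global alignment, and linkage is single: that matches the transitive
behaviour of search-based clusterization, and it guarantees the sweep
is nested (clusters at a higher threshold always refine those at a
lower one — a property the tests assert).  Clusters are ranked by
summed member read counts; "most abundant" is read mass rather than
member count because abundance in this literature is counted in reads.
The label `"<threshold>-<rank>"` (e.g. `40-33` for the 33rd most
abundant cluster at 40% identity) names a family.

The number of genes behind a family is estimated as the number of
single-linkage clusters at 80% identity: members more than 20%
divergent at the amino-acid level are counted as separate genes, and
members within a cluster are read as alleles or near-identical copies.

Conserved blocks are described in a PROSITE-style dashed grammar
(`[FL]-x(2)-[LVMI]-…`) with literal sets, wildcards, repeats and
ranges; the scanner reports every match including overlapping ones and
enumerates every admissible span length of range elements.

## Phylogenetics

Protein sets are aligned progressively (guide order from
average-linkage clustering of pairwise identities; profiles merged by
aligning their consensus sequences and propagating gaps).  Distances
are p-distances — the fraction of differing residues over shared
non-gap columns — because family divergence in this field is quoted as
"% amino acid divergence"; no evolutionary correction is applied.
Trees are canonical neighbor joining (exact on additive distances, a
property the tests verify on random trees), bootstrap support is the
percentage of column-resampled replicates containing each original
bipartition, and clade counting takes *maximal* supported edges with at
least a minimum number of leaves, so nested supported clades are
represented once and members are never double-counted.

## The synthetic generator

`generateFamilies()` builds multigene families from a common ancestral
protein per family.  Its defaults define the simulated study
conditions and what they emulate:

* **Divergence** (`targetAaDivergence = 0.2`): per-codon substitution
  at a rate tuned so independent copies reach the target pairwise
  p-distance (`p = 1 − sqrt(1 − t)`, corrected for the frozen
  initiator/leader prefix).  Family members therefore differ by
  substitutions only — no internal indels or domain rearrangements,
  which real families do show; alignment-heavy stages see easier
  inputs than real data, and the tests say nothing about indel-rich
  family alignment.
* **Signal peptides** (`signalFraction = 0.5`): a hydrophobic leader of
  10–14 residues from {L, V, I, F} after the initiator Met, closed by a
  small residue (A/G/S) — the same grammar the built-in predictor
  recognises.  Non-signal families are constructed so their N-terminal
  region contains no qualifying hydrophobic window; otherwise the
  planted "no signal" label would simply be wrong.
* **Roles**: signal families draw secreted-family keywords, the rest
  housekeeping keywords or (15%) "transposase", giving ground truth for
  classification.
* **Transcripts**: 5′ and 3′ UTRs of about 60 nt flank the coding
  sequence, as in real cDNA; the 5′ UTR is padded to a codon multiple
  and ends in an in-frame stop so upstream Met extension halts at the
  true initiator.  Without UTRs the initiator Met would sit at the very
  first base of the transcript, where shotgun coverage necessarily
  tapers to zero and N-termini would be systematically truncated —
  an artifact of the simulation, not of the method.
* **Expression skew**: log-normal weights (σ = 1), so a run contains
  both abundant and barely-covered transcripts.
* **Lengths**: coding lengths vary ±20% (truncated normal) around the
  450 nt default, typical of secreted salivary proteins.
* **454 errors** (`simulateReads454`): substitutions at 0.5%/base,
  indels at 1%/base scaled by homopolymer run length as
  `rate · (1 + bias · (runlength − 1))` with `bias = 2` — the dominant
  error mode of pyrosequencing and the reason frameshift repair exists.
  The per-base error rates of the original instrument run were not
  published; these defaults are conventions, stated here as such.
* **Qualities**: phred 30 decaying by 0.02/base toward the read end —
  enough structure for the quality-weighted consensus to be exercised,
  not a calibrated instrument model.
* **Strand**: uniform, since library orientation is not modelled.

Every read records its source transcript, coordinates, strand and each
planted edit, so recovery can be scored exactly.  What the generator
does **not** emulate: adaptor/linker chemistry, library normalization
kinetics, chimeric reads, base-composition bias, paralog-specific
expression correlation, and the SFF flowgram representation.  Passing
tests therefore demonstrate algorithmic correctness under controlled
conditions, not instrument-level realism.

## Problem sizes and determinism

The shipped tests and the acceptance script run, by design, at sizes a
laptop handles in minutes: end-to-end runs use 20 families × 3 copies
at depth 15 (≈ 1,500 reads), repair experiments 100 single-indel coding
sequences, clustering and tree properties a few hundred random
instances with ≤ 12 leaves, and bootstraps 200 replicates.  The
original full-scale counts (≈ 1.6 M reads, ≈ 190 k contigs) require the
original dataset and are out of scope.  All stochastic stages take
explicit seeds; a fixed seed reproduces FASTA/qual output and all
tables byte for byte.

## Known limitations

* The greedy assembler is deliberately simpler than CAP3; it has no
  repeat handling and discards insertion-column evidence from the
  minority read at a merge.
* Terminal rescue recovers end fragments only when the consensus still
  encodes them; a contig whose 5' consensus is itself corrupted (too
  few covering reads) stays truncated, and its signal peptide is then
  unrecoverable by any downstream step.
* The e-value surrogate is monotone in score but not calibrated across
  very different sequence lengths.
* The keyword classifier is only as good as its vocabulary; the
  original study additionally applied manual curation, which is
  explicitly not modelled.
* The progressive aligner is adequate for the substitution-only
  synthetic families and for closely related natural families, but it
  is not a replacement for a production MSA tool on gappy inputs.
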