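---
title: "Methods: mitogenome architecture, composition and supermatrix assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome architecture, composition and supermatrix assembly}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the conventions, models and design decisions
behind `mitoarch`. It is the authoritative account of *why* the package
computes what it computes; the README shows *how* to run it.

## Coordinate and strand model

A mitogenome is a circular molecule stored linearized on the majority
(J) strand, with 1-based inclusive coordinates and — following the
lepidopteran convention — `trnM` at position 1 and the A+T-rich
noncoding region (NCR) last. Every derived quantity is plain coordinate
arithmetic on this representation:

* gene size = `to − from + 1`;
* intergenic nucleotides for a junction, `IGN = from(next) − to(prev) − 1`,
  negative for overlaps and positive for spacers;
* the circular NCR→trnM junction is computed but reported separately
  from the linear censuses, because published organization tables omit
  it (for the packaged specs it is 0).

Origin-spanning features are out of scope: with the linearization above
no gene crosses the origin in the genomes this package models. Ambiguity
codes are rejected at genome construction rather than counted, since
every composition formula assumes a strict 4-letter alphabet.

Blank intergenic cells in published organization tables are read as 0
(abutting genes). This is not cosmetic: it is required for the
coordinate-reconstruction bijection (first start + sizes + IGN values
recover every coordinate exactly), which the test suite verifies on the
three packaged specs and on 1,000 random synthetic annotations.

### A documented discrepancy

The source tables for the three skipper genomes imply 10 negative
junctions for *Ampittia virgata*, while the accompanying text counts 11
gene overlaps. The census here reports what the table implies (10); the
package deliberately does not patch either number. Similarly, the text
claims all overlaps span 1–10 bp while the *Halpe nephele* table
contains a 25 bp `trnL1–rrnL` overlap; values are reported verbatim
from the table.

## Start and stop codon classification

Start codons are the first sense-strand triplet, whitelisted as
ATA/ATT/ATG/ATC plus the cox1-style CGA; anything else is flagged
non-canonical but not rejected. Stops are read off the CDS length
modulo 3: a complete TAA/TAG triplet, or the incomplete `T` / `TA`
stops completed to TAA by polyadenylation. Classification problems
(e.g. a frame-complete gene whose last triplet is not a stop) are
recorded in the result, never thrown, so a whole-genome report survives
one odd gene.

Gene *size* includes the incomplete stop nucleotides (matching
published size columns), but pooled protein-coding composition and
codon counting *exclude* them. This is the only convention that
reconciles summed gene sizes with published pooled PCG totals
(11,194 − 4 = 11,190 bp etc. across the three packaged genomes, one
base per single-T stop) and it makes the pool length divisible by
three, which codon-position striping requires.

## Composition statistics

`AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)` are always
computed from raw counts; printing rounds percentages to one decimal
and skews to three, the conventional reporting precision, while full
precision is kept internally. Pooled PCG/tRNA/rRNA statistics use
sense-strand sequences: codon columns in organization tables are
sense-strand, and striping codon positions from J-strand text of an
N-strand gene would scramble them. Whether published pooled tRNA/rRNA
rows used sense or J-strand text is generally not stated; sense-strand
is chosen here and documented — the choice flips skew signs for
N-strand genes but cannot change A+T content. Full-genome statistics
are measured on the J strand. Degenerate inputs are flagged rather than
silently propagated: a region with `A+T = 0` or `G+C = 0` has an
undefined (NaN) skew.

## Relative synonymous codon usage

Codons are tallied in frame 0 with stride 3 over the pooled, trimmed,
sense-strand PCGs. RSCU is the observed count divided by the synonymous
family mean. Families follow translation table 5 (AGA/AGG = Ser,
ATA = Met, TGA = Trp; 62 sense codons) with leucine and serine split
into their two codon boxes (Leu1 = CUN, Leu2 = UUR, Ser1 = AGN,
Ser2 = UCN), the convention used when RSCU is plotted per codon box.
Complete stop codons are counted but excluded from families, so they
never enter RSCU; start codons are counted as ordinary codons (no
special-casing of CGA), because the alternative — dropping position-1
codons — has no precedent in the tables this package mirrors. Ranking
of top codons is deterministic: RSCU descending, raw count descending,
then alphabetical. Codons are DNA-alphabet internally and converted to
RNA spelling (UUA, UCU, ...) only at report boundaries.

## Control-region poly-runs

Published descriptions give ranges (poly-T of 16–22 bp, poly-A of
12–24 bp "often interrupted by the base T"), not a detection rule, so
the rule here is explicit and tunable: a run starts and ends on the run
base, tolerates at most `max_interruptions` consecutive other bases at
a time (default 1), is extended left-greedily to maximality, and is
reported when it contains at least `min_pure` copies of the run base
(default 10). With `max_interruptions = 0` this reduces exactly to
classical homopolymer detection, a property the tests exploit. The
defaults were chosen once so that stretches in the published ranges are
detectable; both knobs are exposed in the API and the CLI. Conserved
sequence motifs of the control region are not modeled — only run
statistics.

## Supermatrix assembly

The three datasets are defined by column selection per gene: `PCG`
keeps all columns of the 13 protein-coding alignments; `PRT` adds the
22 tRNAs and 2 rRNAs; `12PRT` is PRT with every third codon position of
each PCG removed, giving the identity
`length(12PRT) = length(PRT) − length(PCG)/3` that the tests verify on
random gene sets. Codon-position indexing is relative to each gene's
own reading frame after incomplete-stop trimming, never to supermatrix
coordinates. Genes concatenate in canonical genomic order, taxa are
sorted by identifier, and a taxon missing a gene is padded with `-`
(configurable); every output column carries provenance
(gene, source column, codon position), and that map is a bijection onto
the included columns. Alignment itself and block trimming are external
concerns — the package consumes aligned FASTA, because its contribution
is dataset assembly, not alignment. Partition files emit one partition
per gene (a finer scheme can always be merged downstream); with codon
striping requested, PCG partitions use `\3` stride notation, or `\2`
within a 12PRT matrix where third positions no longer exist.

## The synthetic-data generator

The generator exists so that every stage is testable offline. It
separates *architecture* from *content*: the packaged specs fix
coordinates, strands and start/stop codons of the three skipper
genomes exactly, while sequence content is simulated. Hard constraints
(every start codon, every complete or incomplete stop) are written onto
the genome first; protein-coding interiors are then filled codon-wise
from a codon-frequency model restricted to codons consistent with any
bases already fixed by an overlapping gene, with stop codons excluded
so no in-frame premature TAA/TAG can arise; in the rare case where an
overlapping frame still assembles a stop from fixed bases, the fill is
redrawn (bounded retries). Remaining positions are i.i.d. with
`P(A) = P(T) = target_at/2`, default 0.80 — the typical lepidopteran
mitogenome A+T content, recovered within ±0.02 at 15 kb (a binomial
bound the tests check). The control region receives a pure poly-T
stretch (default 19 bp) and a poly-A stretch (default 18 bp with one
single-T interruption), inside the published ranges.

The default codon model multiplies base-composition weights by a
3-fold boost for TTA, TCT and CGA, the codons that dominate RSCU in
skipper mitogenomes, so synthetic usage shows the same qualitative
signature. Where a test needs a *known* usage ranking, it passes an
explicit weight vector instead of relying on the default.

What the generator deliberately does **not** emulate: per-region
composition differences (the real NCR is markedly more A+T-rich than
the genome average; synthetic regions all share one target),
strand-asymmetry (real AT/GC-skew patterns), codon-position-specific
base bias, tRNA secondary structure, and evolution along a tree (the
alignment simulator applies i.i.d. per-site substitutions, with the
per-row rate solved from the requested expected pairwise difference).
Passing tests therefore demonstrate correctness of the *arithmetic and
bookkeeping* on realistic-scale inputs, not fidelity of the sequence
model to real mitogenomes; conversely, every architecture-derived
number (sizes, IGN, censuses, strand counts, pooled lengths) is exact
by construction and independent of the random content.

## File formats

GenBank flatfile and NCBI 5-column feature-table readers/writers are
minimal but round-trip-lossless for the fields they carry; a built-in
synonym table maps the common labels of deposited records (COI, ND4L,
12S, D-loop, tRNA-Leu(UUR), ...) to canonical names, and unknown labels
skip with a warning rather than fail, because deposited records vary.
Both `misc_feature` and `D-loop` keys are accepted for the control
region. FASTA I/O goes through Biostrings; NEXUS through ape; relaxed
PHYLIP (full names, whitespace-separated) and RAxML-style partition
text are written directly. Writers and readers are property-tested as
inverse pairs.

## Command-line interface

The CLI is a thin layer over the exported functions: an R function
(`mito_cli()`) that parses arguments, plus an `exec/mitoarch` script
that calls it. Exit codes are 0 (success), 1 (usage error), 2 (data
error); warnings never change the exit status, and when several genomes
are processed a failure in one is reported while the others proceed.
Every output file begins with comment lines recording the package
version, command, seed, parameters and input checksums, so any table
can be traced to the run that produced it.

## Problem sizes and determinism in the test suite

The suite builds complete 15.3–15.4 kb replicas (cached per test file),
runs property checks on hundreds of random short sequences, 1,000
random annotations for the reconstruction bijection, and ~3 kb
alignments for divergence calibration — sizes chosen so the whole suite
exercises realistic scales while remaining quick. All randomness is
seeded; generator determinism (same profile + seed ⇒ identical genome
text) is itself a tested property.
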