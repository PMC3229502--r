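---
title: "Methods: dinoflagellate genome-survey sequence analysis with dinogss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dinoflagellate genome-survey sequence analysis with dinogss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinogss)
```

dinogss re-implements, as a tested and reusable pipeline, the bespoke
computations of a dinoflagellate genome/transcriptome survey: detection of
spliced-leader (SL) relict cascades at EST 5' ends, discovery of tandem
repeat arrays in clone-end reads with genome-fraction estimation, a
repetitiveness census of a survey read set, stop-codon and polyA-signal
statistics, and in-silico restriction digests. A synthetic-data module
generates inputs with planted ground truth so every stage is testable
without any external download. This vignette explains the models and the
choices behind them.

## The biological setting

Dinoflagellate nuclear mRNAs carry an invariant 22-nt spliced leader (SL)
added by trans-splicing. Mature mRNAs are occasionally reverse-transcribed
and reintegrated into the genome ("mRNA recycling"); upon re-expression, a
new SL is trans-spliced at the AG splice-acceptor site that falls after
nucleotide 7 of the old leader, truncating it to a 15-nt relict. Repeated
cycles therefore stack decaying 15-nt relicts directly downstream of the
canonical SL, oldest (most mutated) furthest 3'. Counting and scoring
these relicts estimates how often a transcript's gene has been recycled.

Dinoflagellate genomes are also enormous (the `genome_size_from_pg()`
conversion, 0.921e9 bp per pg of DNA, puts a 114.9 pg nucleus above 1e11
bp) and, as low-coverage clone-end surveys show, dominated by tandem
arrays of a small set of 79-97 bp units, plus microsatellite-like simple
repeats and low-complexity tracts. dinogss quantifies all of these from a
plain FASTA of reads.

## SL scanning (`find_canonical_sl`, `dedupe_and_trim`, `scan_relict_chain`)

The canonical SL is located by scoring every 22-nt window that lies fully
within the first 60 bases of an EST against an IUPAC consensus
(`sl_config()`; the default is the conserved dinoflagellate SL, which
starts with the ambiguity code `D` and ends `CAAG`). The best window at or
above `canonical_min_identity` (default 0.90, i.e. at most two
mismatches) is taken, leftmost on ties. SL-bearing ESTs are then trimmed
to start at the SL and deduplicated: a trimmed sequence that matches a
longer one at >= 95% identity over the full overlap is collapsed onto the
longest representative. The published redundancy criterion is not stated
precisely; prefix-collapse at 95% is our choice and is exercised against
generator truth.

Relict copies are chained greedily 5' to 3'. From the end of the previous
copy (initially the canonical SL end), start offsets `0..max_offset`
(default 3, allowing the small indels visible between relicts in real
alignments) are examined; at each offset a 15-nt window is scored against
the relict motif (the consensus truncated after nucleotide 7) and the
highest-identity window at or above `relict_floor` (default 0.50,
mirroring a search "from 100% down to 50% identity") is accepted, ties to
the smallest offset. Identity is ungapped throughout: 15-mers within 50%
divergence rarely need gaps, and ungapped scores are exactly
oracle-checkable. A single floor is used for all ranks because the
published per-rank identity ranges are outcomes of the search, not
cutoffs.

### The false-acceptance floor

A design consequence worth stating precisely: under a uniform base model a
random 15-nt window reaches 8/15 matches (the smallest identity at or
above 0.50) with probability `1 - pbinom(7, 15, 0.25)` = 0.0173. One
chain step takes the maximum over `max_offset + 1 = 4` near-independent
windows, so the per-step false-acceptance probability is about
`1 - (1 - 0.0173)^4` = 0.067. Every EST's chain ends with exactly one
such step into non-relict sequence, so roughly 6-7% of ESTs are expected
to gain one spurious relict, independent of their true depth. The
property suite measures the realised null rate on relict-free synthetic
ESTs and checks it against this prediction. The practical reading: with
the default floor and offset slack, per-EST depth is accurate to about
93-94%, and aggregate depth histograms should be interpreted with this
one-sided (over-calling) error in mind. Raising `relict_floor` or setting
`max_offset = 0` makes the call conservative at the cost of missing
degenerate or displaced relicts.

## Tandem arrays (`detect_period`, `extract_unit_consensus`, `annotate_arrays`)

Period detection is by exhaustive self-comparison: for each candidate lag
`p` (default 20-300 bp, bracketing the published 79-97 bp units with
margin) the mean ungapped identity between the sequence and itself
shifted by `p` is computed; the best lag qualifies when that identity
reaches 0.85. An exhaustive lag scan is simple, exactly testable, and
entirely adequate at clone-end read scale (<= 1.2 kb). Within a read,
array regions are localised by a windowed version of the same statistic
(windows of one unit length), overlapping period candidates are resolved
in favour of the longest span with a preference for the smallest period
(so a true period is not reported as its own multiple), and the unit
consensus is extracted by per-column majority vote. The frame phase is
chosen to maximise the number of complete units (ties by copy-consensus
identity, then the smallest phase); a full phase search maximising mean
inter-copy identity would change only partial boundary units while
dominating runtime at survey scale. Copies below `divergent_floor`
(default 0.85, generously admitting the 88-98%-identity divergent copies
seen in real arrays) are trimmed from the array edges.

Arrays whose consensus is itself near-periodic at lag 1-6 are excluded
(`exclude_simple_units = TRUE`): a microsatellite tiling self-matches at
every multiple of its short period, and those regions belong to the
simple-repeat category of the census, not to the complex tandem arrays.

Family grouping compares unit consensi circularly: the shorter unit is
slid over the doubled longer unit on both strands and the two units merge
when the best full-length identity reaches 0.90. This is the same
80%-coverage / 90%-identity idea as a shared-segment criterion, made
affordable for thousands of arrays; `shared_segment()` itself (sliding
ungapped window search, both strands) is retained for detailed unit-pair
comparison, e.g. the 60-bp / 93%-identity overlap between two of the
reference units in `aost_repeat_units()`.

The genome fraction of a family follows the survey's accounting:
`100 * sum(n_units * unit_length * n_reads) / total_bp`, with fractional
trailing units counted as complete units only when complete
(`floor`). Counting is per read here (each read is its own "contig" with
`n_reads = 1`) unless the caller aggregates reads into contigs first; the
original computation counted per contig consensus.

`in_silico_digest()` cuts at every occurrence of a recognition site on
either strand, at the site start rather than the enzyme's true cut
offset: only the fragment-ladder periodicity matters for verifying that a
clone consists of tandem repeats (a one-cut-per-unit enzyme collapses the
insert to unit-length fragments), not the few-bp offset.

## The repetitiveness census (`greedy_overlap_cluster`, `feature_census`)

The survey used assembly software only to identify non-unique sequence
stretches, so dinogss replaces assembly with greedy overlap clustering:
reads sharing an ungapped overlap of at least `min_overlap` bp at
`min_identity` (genomic preset 100 bp / 0.90; EST preset 40 bp / 0.95
with at most 30 mismatches) with any cluster member join that cluster,
in either orientation at any offset. Candidates are seeded by exact
16-mer matches and verified over the full implied overlap; membership is
the connected components of verified overlaps, so it is invariant to
input order, and cluster numbering follows the longest-read-first,
then-lexicographic seed order. Singleton reads are `unique`, clusters of
two or more are `repetitive`, and clusters of more than 20 reads are
`highly_repetitive`. The published clustering was gapped (an assembler);
the ungapped approximation is documented, not asserted equivalent.

Simple repeats (units of 1-6 bp spanning >= 12 bp with >= 90% of
positions in phase, reported as the minimal rotation of the primitive
unit) and low-complexity tracts (64-bp windows with mononucleotide
Shannon entropy below 1.5 bits, merged and labelled by dominant bases)
are annotated per read. For the census, interval features annotate a
whole read when they cover at least half of it; repetitiveness features
annotate whole reads by construction. `feature_census()` then reproduces
the survey's double accounting: each read contributes its full length to
every feature it carries, `pct_actual` divides by the true sample bp
while `pct_pie` divides by the (overestimating) sum of per-feature bp.
Database-dependent categories (genes, tRNA-derived, transposons,
satellites) are accepted as external pass-through labels and never
computed.

## Coding statistics (`infer_stop_codon`, `polya_motif_scan`)

Stop codons are read directly off the frame when a frame hint exists,
otherwise from the longest start-to-stop ORF over the three forward
frames, searching only 5' of the detectable polyA tail. Percentages use
conventional round-half-up at the table's printed precision.

The polyA-signal search is an exhaustive k-mer census of the `window` bp
(60 by default, 30 as the published alternative) upstream of each polyA
start: observed counts of every 5-9-mer are compared with expectations
under a per-sequence base-composition background (positions independent;
a first-order Markov background is available via `background = "di"`),
with a one-sided binomial p-value. The published search used an HMM
pattern tool and reported a negative result; exhaustive enumeration is
exact, tool-free, and reproduces the negative-result behaviour on matched
nulls. Significance is Bonferroni-controlled over *every* motif the scan
interrogates (the sum of 4^k across k = 5..9, about 3.5e5 motifs), not
per motif size: the scientific claim a negative scan supports is "nothing
in the whole search was enriched", which requires experiment-wise
control; per-size control alone would let the union of five families
exceed the nominal error rate several-fold.

PolyA tails are located as the 3'-terminal A-run of at least 10 bases; a
pure terminal run takes precedence, and up to one non-A base is tolerated
inside the run otherwise (sequencing error). If the base 5' of a tail is
itself an A, the reported start extends into it -- the run, not the
ligation point, is the observable.

## The synthetic-data generators

`generate_sl_ests()` emulates the EST structure the SL analysis assumes:
a resolved SL consensus, `depth` relict copies with
`Binomial(15, rank * rate)` substitutions (mutation cumulative with rank,
matching the observed progressive decay; default depth distribution
0.74/0.21/0.04/0.008/0.002 echoing the published cascade counts, default
rate 5% per cycle), then a GC-0.55 UTR/CDS tail (the published nuclear
EST GC) and a polyA tail preceded by a non-A base so planted tail starts
are unambiguous.

`generate_gss_reads()` draws 300-1200 bp reads (a typical Sanger
clone-end range; the source survey does not print its distribution) from
a composition over tandem families (defaults: the four reference units at
their published genome shares, about 58% in total), simple repeats (13%),
low-complexity tracts (8%) and unique background (the remainder) at 60%
GC. Tandem reads are random-phase tilings in which each copy is divergent
(2-12% substitution, the published 88-98% identity band) with probability
0.25 and carries 0.5% sequencing-style noise otherwise -- the published
arrays are a major repeat type *interspersed with* divergent copies, not
uniformly divergent; an all-copies-divergent model would put adjacent-copy
identity at ~0.87, straddling the 0.85 detection threshold and making
period detection fail on a large minority of reads by construction.
Low-complexity styles are dominant-pair compositions (GA-, GC-, CT-rich,
entropy ~1.4 bits): a single-base-dominant composition such as C-rich
unavoidably contains homopolymer runs that are bona fide simple repeats,
which would make the planted categories inseparable.

`generate_cds_set()` plants stop codons from a chosen distribution
(default: the published TAA/TAG/TGA proportions 7.2/16.5/76.3%), draws
codon third positions G/C with probability `gc3` (default 0.8, a strong
GC3 bias), and appends UTR and polyA tails.

All generators seed their own RNG stream from `seed` and restore the
caller's RNG state, so adding one generator call never perturbs another
and a given call is byte-reproducible.

What the generators do *not* emulate: base-call quality and chromatogram
artifacts, cloning-vector contamination, hydroxymethyluracil and other
modified bases, gapped divergence (indels) inside arrays and relicts, and
real transcript families with shared domains. Passing recovery suites on
this synthetic data therefore demonstrates that the algorithms implement
their contracts and recover planted structure under realistic point-noise
-- not that thresholds tuned here are optimal for chromatogram-derived
reads.

## Numerical and interface conventions

Coordinates are 0-based half-open everywhere. Percentages printed for
table comparison use round-half-up at the printed precision. `N` matches
nothing in identity scores and is excluded from GC content (all-`N` GC is
`NA` with a warning). `U` is mapped to `T` on input; lowercase is
uppercased. Ties break deterministically throughout: leftmost window,
smallest offset, smallest period, alphabetical consensus base, longest
read then lexicographic id. Problem sizes in the test suite (500 ESTs for
cascade recovery, 2,000 reads for family-fraction recovery, 1,000 CDS for
stop-codon recovery, 100 null replicates for the motif scan) keep every
suite in seconds-to-minutes on one CPU while leaving binomial sampling
error well inside each tolerance.

## Known limitations

* Identity is ungapped everywhere; the original workflows used gapped
  tools in places (assembler clustering, SL search), so absolute counts
  on real data may differ at the margins.
* Greedy clustering gives membership counts, not consensus contigs;
  family fractions counted per read differ from per-contig counting when
  coverage is uneven.
* The relict-chain over-calling floor described above is intrinsic to a
  50% floor with offset slack on 15-mers.
* The full-scale published counts (12,287 ESTs; 4,709 usable reads; 238
  unique SL transcripts) depend on the deposited raw data and are not
  reproduced here; everything derivable from printed sequences, counts
  and formulas is.
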