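---
title: "Methods: MITE landscape annotation in mitescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MITE landscape annotation in mitescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitescape)
```

Miniature inverted-repeat transposable elements (MITEs) are short
(< 700 bp) non-autonomous Class II transposons. They carry no coding
capacity, are bounded by terminal inverted repeats (TIRs), and are flanked
by a target site duplication (TSD) created at insertion. Because the TSD
length and sequence are characteristic of the mobilizing superfamily —
TA for *Stowaway*/Tc1-mariner, TAA/TTA for *Tourist*/PIF-Harbinger, 8 bp
for *hAT*, 9–10 bp for *Mutator* — structural features alone carry a lot
of classification signal. This vignette documents the models, thresholds
and design choices behind each stage of the package, and what the
synthetic-data tests do and do not demonstrate.

## Copy detection

Given a family consensus and a genome, `local_align_all()` performs an
exhaustive Smith–Waterman scan on both strands. The scoring scheme is
fixed at match +1, mismatch −1, linear gap −2; sequence letters outside
ACGT are normalized to N and never match. The scan is exact, not
seeded: a compiled first pass records the best local score ending at every
subject position in O(genome × consensus) time and O(consensus) memory;
candidate regions are then re-aligned with full traceback, and
non-overlapping alignments are extracted greedily by score (ties break to
the smallest subject, then query, end coordinate; traceback prefers
diagonal over subject-gap over query-gap moves). Alignments are extracted
down to a score floor of `max(16, 0.3 × min_len)` and then filtered by the
explicit identity/length thresholds, so the floor only bounds work, not
the reported hit set. Because the scan is exhaustive, the hit set can be —
and in the test suite is — compared *exactly* against an independent
Smith–Waterman implementation (Biostrings with N-masking between
extractions).

A hit is accepted as a full-length copy under the 80-80-80 rule with end
anchoring (`filter_full_length()`): identity ≥ 80 %, alignment length
≥ 80 bp, alignment covering ≥ 80 % of the consensus, and the alignment
starting within 1–10 nt of **both** consensus ends. The offsets are
counted on the consensus; whether the original rule counted query or
subject offsets is not determinable from its statement, and the consensus
reading is the stricter, more reproducible choice. Rejected hits are kept
with a reason code.

Overlap resolution across families (`resolve_overlaps()`) is a package
decision: among copies overlapping by more than half the shorter span, the
copy maximizing identity × coverage wins; exact ties go to the
lexicographically smaller family name so the output is deterministic.

Accepted spans are finally projected to the full consensus extent: since
both ends anchor within 10 nt, an unaligned overhang is diverged terminal
sequence rather than missing sequence, and the projection keeps the
flanking TSD in register for structure calling. The projection assumes
substitution-dominated ends; a terminal indel can shift a boundary by its
length.

## Structure calling and classification

`detect_tsd()` compares the k-mers immediately left and right of the
element for k in (10, 9, 8, 3, 2); the first match wins. Short TSDs (2–3
bp) must match exactly — at that length a single mismatch is
indistinguishable from chance — while k ≥ 8 tolerates one mismatch.
A `(TA)3` run immediately adjacent on either side raises the `ta_stretch`
flag. Inside a microsatellite the duplication length is inherently
ambiguous (every even k matches), which is why MiM recognition rests on
the stretch flag rather than on k.

`detect_tir()` scans arm lengths 8–50 and reports the arm maximizing the
*ungapped* identity between the leading arm and the reverse complement of
the trailing arm (ties to the longer arm). A TIR is recognized at
identity ≥ 80 % and arm ≥ 10 nt. These thresholds are configurable; they
were chosen so that random 300-mers essentially never show a recognized
TIR (empirical null in the test suite) while one or two substitutions in
a true arm do not destroy the call.

`classify_superfamily()` applies the canonical TSD table. The MiM rule —
TA-stretch flank *and* TIR identity < 80 % — is evaluated **before** the
table: a MiM sitting in (TA)n necessarily displays a TA duplication and
would otherwise be absorbed into *Stowaway*. MiMs are reported as their
own superfamily but pooled with *Mutator*-like in group summaries,
reflecting their attribution to that superfamily.

`cluster_families()` implements 80-80-80 family grouping as single-linkage
connected components. The rule defines a pairwise relation, not a
partition; single linkage is the only closure consistent with merging
redundant consensi transitively, and it makes the partition
order-invariant (tested by permutation).

`mine_autonomous()` searches all six translation frames against protein
queries under BLOSUM62 (local alignment, gap open 11 / extend 1, score
≥ 100), merges hit regions, and looks for an inverted-repeat arm pair in
the ± 4 kb flanks. The arm search is an *ungapped* local alignment of the
left flank against the reverse complement of the right flank (match +1,
mismatch −1), consistent with the ungapped TIR convention; accepted arms
need identity ≥ 50 %, length ≥ 20 bp, and score ≥ 20. The score floor is
a significance guard: in 4-kb random flanks, gapped or low-scoring
alignments of 20–90 columns at 50–70 % identity arise by chance, and the
floor keeps them from defining spurious element boundaries while a perfect
20-bp arm still passes exactly. Element boundaries are the outermost arm
coordinates; regions without an acceptable pair are reported as
candidates without boundaries.

## Genomic context

`categorize_copies()` assigns exactly one category per copy in the priority
order 5′UTR, 3′UTR, CDS, intron, upstream, downstream, intergenic. UTR and
CDS require any overlap ("overlapping"), intron requires full containment
("located within"), so boundary-straddling copies fall through to the next
rule. Upstream/downstream are strand-aware 1-kb windows measured from the
gene's 5′/3′ edge with an inclusive distance (gap ≤ 1000 bp); a copy that
straddles the gene edge without matching a higher-priority feature is
assigned at distance 0. A copy near several genes takes the
highest-priority category, with distance breaking ties at equal priority.
Genes with multiple mRNA isoforms are collapsed to the union model (exon
union, UTR unions, intron space = gene span minus exon union) because
categorization is per gene, not per isoform.

`enrichment_chisq()` is the classic Pearson test of independence on the
group × category table, with per-cell contributions (O−E)²/E and deviation
signs retained for balloon-plot summaries; `stats::chisq.test()` (no
continuity correction) supplies the statistic and is cross-checked against
the textbook formula in the tests. The genic fraction is
100 × (total − intergenic)/total, with the nearest-integer rounding used
in summary tables.

## Expression statistics

All expression quantities derive from normalized RPK,
`(count/(length/1000)) / (library_size/1e6)`, which is invariant to
library-size rescaling. The co-transcription filter keeps copies with
≥ 10 matched reads, pooled across libraries by default (a per-library mode
exists; pooling is the more permissive reading and the one used in
summaries). Read matching requires a best local alignment longer than
20 bp with identity above 80 % — both strict.

M/g divides the MITE segment's normalized RPK by the host gene's. The
gene denominator uses all reads on the gene span *including* the MITE
segment — the subset semantics are stated rather than assumed — and the
RPK > 1 gene filter applies to normalized RPK by default (a raw-RPK flag
exists). Selection requires gene RPK > 1 and M/g > 1.9, strictly;
tissue-differential genes additionally need max(M/g) − min(M/g) > 1.5
across at least two libraries.

## Cross-species comparison

`family_match()` takes the best local alignment between two consensi
(either strand) and computes coverage against each sequence's own length;
the pair is related when identity ≥ 60 % and coverage ≥ 60 % in either
direction. The disjunction makes the relation symmetric, which the
sharing summaries assume. No transitive closure is applied across
species: each claimed sharing is a direct match. The score-ratio coloring
bins (0.25/0.50/0.75) are computed from identity × coverage, an
approximation to alignment-score ratios noted as such.

## The synthetic-data generator

`simulate_mite_genome()` emulates the inputs the analysis consumes, with
ground truth recorded at generation time:

* a uniform-random genome (default 2 Mb in two contigs) — no GC structure,
  no repeats beyond what is planted;
* eight family blueprints spanning the five groups, consensi ≤ 700 bp with
  perfect TIR arms (MiM arms degraded to ~50 % identity, evenly, so no
  short window looks conserved);
* 25 copies per family at 10 % divergence (i.i.d. substitutions on the
  element only; flanks and TSDs stay intact), planted non-nested at
  uniformly sampled sites, with superfamily-appropriate TSDs. *Stowaway*/
  *Tourist* copies insert their canonical duplication; *hAT*/*Mutator*
  copies duplicate the host k-mer at the site, matching transposition
  biology; MiM copies are planted inside generated (TA)5 stretches.
  Planting can be directed at a target context category, with one copy per
  upstream/downstream window so a later insertion cannot silently push an
  earlier copy out of its 1-kb window;
* gene models with 2–4 exons, strand-aware UTRs and derived introns, laid
  out so that neighboring 1-kb windows never collide;
* Poisson read counts over genes and MITE segments whose expectations
  realize a requested M/g (default 2.5) given each library's size. The
  Poisson choice is a package decision; no noise model is prescribed by
  the procedure being implemented.

Fixed seeds make every output byte-identical. The standard problem sizes
used in the checks — 2 Mb / 8 × 25 copies for recovery, ~0.4 Mb bundles
for module tests — were chosen as the smallest sizes at which the
stochastic properties (recovery ≥ 95 %, M/g within 10 %) are comfortably
stable.

What passing these tests shows: the detector recovers planted copies with
exact spans at ≤ 15 % divergence, classification is perfect when flanks
and arms are unmutated, context categories match construction, and the
expression statistics are unbiased at high coverage. What they do not
show: behavior on real genomes with nested/truncated insertions,
segmental duplications, diverged TSDs, sequencing error, or spliced reads
— the generator deliberately excludes all of these (non-goals), so real
data will be messier than the synthetic floor suggests.

## Numerical choices and degenerate inputs

* Alignment identity is matches / alignment columns (gaps included).
* Greedy hit extraction masks subject columns after each alignment; ties
  are broken deterministically (documented above) so runs are reproducible.
* `enrichment_chisq()` refuses tables with a zero margin or fewer than two
  non-empty rows/columns; `genic_fraction()` refuses empty tables;
  zero-length features and zero library sizes are parameter errors; a gene
  with zero expression yields an undefined (NA) M/g that is never
  selected.
* Copies clipped at contig edges get shortened flanks; TSD calling returns
  "no call" (k = 0) when flanks are shorter than 2 nt.
* All internal coordinates are 0-based half-open; GFF3 is read and written
  1-based closed; BED is written 0-based half-open.

## Known limitations

* Terminal indels in a copy shift the projected span by their length.
* The arm-search score floor (≥ 20) means genuinely degenerate autonomous
  TIRs (e.g. 30 bp at 55 % identity) are reported as candidates without
  boundaries rather than risking noise-defined boundaries.
* The pairwise clustering and cross-species comparison are O(n²) in the
  number of consensi; they are meant for curated libraries (hundreds), not
  raw repeat catalogs.
* MiM TSDs are reported as the longest matching duplication (k = 10 inside
  a TA stretch), which is a property of microsatellites, not an error —
  classification therefore keys on the TA-stretch flag.
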