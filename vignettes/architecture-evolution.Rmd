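---
title: "Models and methods: exon-intron architecture evolution with intronarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: exon-intron architecture evolution with intronarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronarch)
```

## Scope

`intronarch` analyzes how the exon-intron architecture of a single-copy
gene evolves across a set of taxa: descriptive per-gene metrics (length,
GC content by codon position, splice-site census, intron-length
distributions), homologization of intron positions across taxa, ancestral
reconstruction of intron gains and losses on a species tree, detection of
partial gene duplications, quantification of transposable-element (TE)
content, and classification of alternative-splicing events. Because real
multi-genome datasets of this kind are assembled from dozens of public
genomes and cannot be bundled, the package ships a simulator that evolves
an ortholog family along a tree while logging every event, so the whole
pipeline can be exercised against a known truth.

All internal coordinates are 0-based half-open; GFF3/GTF (1-based
inclusive) conversions are confined to the parsers and writers.
Minus-strand genes are normalized at parse time so exon 1 is always the
first transcribed exon; all downstream analyses are strand-agnostic.

## Intron-site homology

Intron positions are compared across taxa in protein-alignment
coordinates. Each intron is reduced to the codon it interrupts
(`codon_index = floor(cds_offset / 3)`) and its phase
(`cds_offset mod 3`: phase 0 between codons, phase 1/2 inside a codon),
and the codon index is mapped through the taxon's gap pattern to an
alignment column. Positions sharing a phase whose columns lie within
`column_tolerance` of one another (single linkage) form one homologous
site. The default tolerance is 0 -- only identical columns merge -- which
is conservative and appropriate for well-conserved coding regions; it is
configurable for noisier alignments, and merging two introns of one gene
into one site is treated as an error (the tolerance is too loose) rather
than silently resolved.

When no alignment is supplied, proteins are star-aligned around the
longest sequence with pairwise global alignments (BLOSUM62, gap open 10,
gap extend 1) merged under the once-a-gap-always-a-gap rule. A star
alignment is deterministic and adequate for closely conserved proteins;
for divergent data a proper MSA should be supplied and is used verbatim.

Site labels follow the field's convention: sites present in a reference
complement (by default the root's reconstructed complement) are numbered
1..k in alignment order, and a derived site absent from the reference is
labeled with the preceding reference number plus a prime (e.g. `21'`).

## Gain/loss reconstruction

The default reconstruction is Dollo parsimony with the root state
constrained to absent: each site is gained exactly once -- on the branch
entering the most recent common ancestor (MRCA) of all carriers -- and
lost freely on the maximal carrier-free subtrees below that node. This
matches the biological prior that parallel gain of an intron at the same
position and phase is far rarer than loss, and it encodes the assumption
that the intronless state is ancestral. A gain whose MRCA is the root is
reported as "gained at or before the root", since no outgroup state
exists inside the matrix. Taxa with a missing gene are excluded per site
(absence of evidence is not intron loss): a subtree containing only
missing-data leaves never receives a loss event.

A constrained Fitch alternative (unit-cost Sankoff with the root forced
absent, ACCTRAN or DELTRAN tie-breaking) is provided; sites whose event
placement differs between the two methods can be flagged as
low-confidence with `flag_method_sensitive()`. Both methods are verified
in the test suite against exhaustive enumeration of all internal-node
labelings on every rooted tree shape with up to six leaves.

Two limits of any matrix-based reconstruction are worth stating
explicitly, because they bound what event-recovery experiments can show.
First, losses that occur in parallel on sister branches are merged by
parsimony into a single loss on the parent branch (one event instead of
two). Second, a site lost along an entire root-child subtree is
indistinguishable from a site gained on the other root child (one gain
beats root gain plus loss). Simulated histories that contain such events
are therefore recovered only up to these equivalences; in the package's
16-leaf recovery experiment (gain 0.1, loss 0.3 per branch, 20
replicates) this caps exact event recall at roughly 92%.

## Descriptive metrics

GC content excludes IUPAC ambiguity codes from numerator and denominator,
so N-rich draft sequence does not bias estimates; a sequence with no
unambiguous base yields `NA`, never 0. GC1/GC2/GC3 are computed over
complete codons only (a trailing partial codon is dropped with a
warning). The splice-site census records the terminal dinucleotides of
each intron on the transcription strand; GT-AG is canonical and
everything else is typed as `XX-YY`. Introns shorter than 4 nt cannot
carry two dinucleotides and are flagged invalid and excluded from
totals. The census counts per sequence (gene copy), not per species, so
multi-copy taxa contribute each copy. Intron-length bins use strict lower
bounds: "larger than 5 kb" means > 5000 nt; percentages in report tables
are rendered with two decimals while internal values keep full precision.

## Partial-duplication scan

Each exon is searched against the gene and its flanking sequence
(seed-and-extend): exact 11-mer seeds from a rolling-hash index of the
scanned frame, merged into diagonal-banded candidate windows, refined by
Smith-Waterman local alignment (match +2, mismatch -3, gap open -5, gap
extend -2; the first gap character costs open + extend, following the
Biostrings convention). Hits must reach 70% identity over aligned
columns, 50% query coverage, and an alignment score of 30. The score
cutoff is the Karlin-Altschul point at which the expected number of
chance hits on a megabase-scale frame falls below 0.01 for this scoring
scheme: it admits any full-length match of an exon of ~16 nt or more
while rejecting chance extensions of single seeds, whose scores plateau
near 28. Exons shorter than the seed length are skipped with a warning;
consequently, duplication spans whose terminal exons are very short
(< ~16 nt) are reported with those exons trimmed.

Hits from all exons are sorted by position and chained when exon indices
increase strictly (or decrease strictly, for inverted copies on the minus
strand) within a 20 kb gap. A chain is never extended so that its merged
interval would span one of its own source exons -- a duplicate copy
cannot contain its source -- which keeps chance hits from bridging across
the gene body. Blocks fully inside intron *i* are classified
`internal(i)`; blocks beyond the gene ends are `upstream`/`downstream`
with their distance to the gene; a block straddling an exon boundary is
assigned the intron containing its midpoint and flagged. A block is
`full` only if it spans every exon; anything else is a partial
duplication. The default flank reach is whatever sequence is provided in
the scanned frame; the simulator sizes flanks to cover planted
duplications up to hundreds of kb upstream, mirroring the distances at
which real flanking copies have been reported.

## TE content and correlations

TE fractions are computed on interval unions, so overlapping or
fragmented annotations never double-count, and an element reported as two
abutting records contributes exactly its length. Class composition
resolves inter-class overlaps by the priority retrotransposon > DNA
transposon > helitron > unclassified (RepeatMasker output is normally
non-overlapping; the rule only guards pathological inputs). The fraction
denominator is the full gene length by default, with an intron-only
denominator available. Pearson correlations are computed from the
closed form (r, then `t = r*sqrt((n-2)/(1-r^2))` on n-2 df, two-sided);
the gene-length ~ TE-fraction test is reported both over all profiled
genes and excluding TE-free genes, since published analyses are ambiguous
on that choice, and p-values are reported raw (only two planned tests).

## Alternative splicing and uORFs

Transcript pairs are compared by their intron chains within the shared
genomic span; differing introns are grouped into overlapping event
regions and typed: shifted donor only (`alt_donor`), shifted acceptor
only (`alt_acceptor`), two introns fused across an internal exon
(`exon_skipping`), two non-overlapping internal exons each unique to one
transcript between shared flanks (`mutually_exclusive`), an intron of one
transcript inside an exon of the other (`intron_retention`), and
everything else `other`. Alternative first-exon usage -- identical chains
inside the shared span while exactly one transcript splices additional
introns outside it -- is deliberately filed under `other`: the literature
itself labels such isoforms inconsistently (exon skipping vs alternative
first exon), so the classifier stays literal. Events identical across
pairs are deduplicated. uORFs are ATG-initiated ORFs in any frame lying
entirely upstream of the main start; lengths count the initiator Met and
exclude the stop.

## The simulator

`simulate_family()` builds an ancestral gene and walks the tree,
recording every event. Defaults describe a conserved seed-plant-like
coding gene: 23 exons (22 ancestral intron sites), a 3,498 nt CDS
(within the 3.3-3.8 kb range typical of the conserved orthologs that
motivate the package), lognormal base introns (median ~250 nt, minimum
60 nt), gain 0.1 and loss 0.3 events per branch (losses dominating, as
observed in seed plants), CDS substitution 0.005 per site per branch with
a 3:1 bias to third codon positions and rejection of nonsense changes (so
proteins stay alignable), and a 5.95% non-canonical splice-site
probability dominated by GG-CA -- the non-canonical rate and type ranking
reported for the real gene family. TE insertions (0.3 per branch by
default; configurable per taxon on terminal branches) paste a mutated
copy of one of five small synthetic consensus sequences (Gypsy- and
Copia-labeled LTR retrotransposons, a DNA transposon, a helitron, and an
unclassified element, weighted toward Gypsy) into a random intron,
splitting any TE record the insertion lands inside -- the fragmentation
pattern real annotators produce. Planted duplications copy an exon span
(with its introns) into a named intron or flank at a set divergence;
isoform operations derive alternative transcripts by named edits (skip an
exon, shift a donor/acceptor, retain an intron, swap in a mutually
exclusive exon, or change the first exon).

What the simulator does *not* emulate: indels in coding sequence (so true
alignments are trivial and star alignment is exact), intron sliding,
nested gene structures, GC-content heterogeneity along the gene, and
TE age structure. Passing recovery tests therefore demonstrates the
correctness of the pipeline's bookkeeping and inference on clean,
well-posed inputs -- not robustness to annotation error or alignment
ambiguity in real genomes, where a user-supplied curated MSA and manual
inspection of low-confidence sites remain necessary.

Determinism: all randomness flows from `sim_config(seed=)` through R's
RNG in a fixed traversal order; two runs with one seed produce
byte-identical output files.

## Problem sizes in the test suite

The suite runs the parsimony oracle over every rooted tree shape with up
to 6 leaves and all non-trivial presence patterns; event recovery over
twenty 16-leaf replicates; duplication recovery over ten planted
duplications (spans of 3-14 exons; internal targets and flank targets
out to 341 kb upstream) at 0% and 10% divergence; the TE-length
correlation over 30 taxa with terminal-branch insertion rates spanning 0
to 30 events; and 1,000 randomized oracle comparisons for positional GC
and seeded alignment. These sizes keep the full suite under a few
minutes while covering each inference path end to end.

## Known limitations

* The star aligner is a fallback for conserved proteins, not a general
  MSA method; divergent families need an external alignment.
* Homology across taxa with radically different intron counts (0-27)
  will produce many taxon-unique sites at tolerance 0; no attempt is made
  to merge them, because no defensible criterion exists without
  nucleotide-level evidence.
* Event recovery is bounded by parsimony identifiability, as described
  above.
* Duplication spans are reported over exons detectable at the score
  cutoff; terminal micro-exons may be trimmed from a span.
* The AS classifier is pairwise; multi-transcript events are reported as
  their deduplicated pairwise decomposition.
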