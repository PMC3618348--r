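---
title: "plastomekit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastomekit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plastomekit reconstructs and compares circular plastid genomes (plastomes)
from total-DNA shotgun reads, and ships a synthetic-data generator so that
every pipeline stage can be exercised against known truth without any
downloads. This vignette records the scientific model behind each stage, the
parameters that matter, and the design decisions taken where reasonable
alternatives existed.

## The object of study

A typical grass plastome is a circular molecule of roughly 130-136 kb with a
quadripartite architecture: a large single-copy region (LSC, ~80 kb) and a
small single-copy region (SSC, ~12.5 kb) separated by two identical inverted
repeat copies (IRa/IRb, ~21.5 kb each). About 54% of the molecule is gene
space (exons of protein, tRNA and rRNA genes, genes in the IR counting
twice), ~12% introns and ~34% intergenic spacers. The region between *rbcL*
and *psaI* in the LSC is a mutational hot-spot in grasses: it carries eroding
pseudogene remnants (an *rpl23* translocation trace, an *accD* remnant) that
are progressively removed by medium-sized deletions, and its length varies
between species accordingly.

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted exactly once at the I/O boundary. Position 0 is
defined as the first base of the LSC, with the LSC on the forward strand.

## The synthetic world

`generate_plastome()` packs a declared gene inventory into the LSC, IRb and
SSC in inventory order, separated by i.i.d. uniform A/C/G/T filler, then
completes the circle as LSC + IRb + SSC + IRa with IRa the exact reverse
complement of IRb. The default inventory mirrors published grass-plastome
bookkeeping: 114 distinct genes of which 82 sit in the LSC, 12 in the SSC
and 20 in the IR (hence 134 annotated gene copies), with exon/intron budgets
balanced so the default 79,972/12,428/21,441 geometry lands at approximately
54.34% gene, 11.91% intron and 33.75% intergenic space. Protein genes are
generated as clean reading frames (ATG start, in-frame terminal stop, no
internal stop), so reading-frame-based pseudogene calls have a meaningful
baseline; the planted *accD* remnant is deliberately random sequence, i.e. a
degraded frame. Two details are worth knowing:

* Boundary filler bases are adjusted (at most one base per region edge) so
  that the planted IR pair is *maximal* - it cannot be extended by a chance
  complementary base across a region boundary. Without this, IR detection
  would legitimately report a repeat one base longer than planted, with
  probability about 1/4 per boundary.
* Real intergenic spacers and codon usage are not modelled; the filler is
  uniform. Consequently a green test establishes algorithmic correctness on
  realistic *geometry* and *divergence*, not robustness to biological
  sequence composition (GC skew, homopolymers, microsatellites).

`evolve_genome()` derives descendant species. Structured events (named
deletions, pseudogene ablations, planted SNPs) are applied first, in list
order; stochastic substitutions and 1-10 bp indels are then drawn at
per-base rates, never inside structured deletions. Every event carries
parent coordinates, and replaying the ordered log (descending coordinate)
reproduces the child byte-for-byte; this replay is the definitional oracle
used by the tests for length arithmetic and feature lift-over. A deletion
covering a feature removes it; partial overlap truncates and flags it.

`simulate_reads()` samples fragments uniformly on the circle (wrapping the
origin), with Normal(insert_mean = 200, sd = 20) insert sizes, paired
100 bp reads by default (the read length of the emulated libraries is not
fixed by the protocol, so it is configuration, not a constant),
per-base substitution errors at a configurable rate, and PHRED qualities
(discrete 2-40) whose mean decays linearly toward the 3' end - the standard
short-read quality profile. Contaminant genomes (e.g. soil bacteria, whose
abundance depends on the source tissue) contribute pairs at declared
fractions, and every pair keeps a truth label.

## Read quality control

A read is flagged if it has (i) a run of more than three consecutive N
calls, (ii) more than three bases at PHRED <= 20, or (iii) a median PHRED
below 20 (lower-middle convention for even lengths, since scores are
integers). The original filtering script's trimming direction is not
recoverable, so the package trims from the 3' end to the longest prefix on
which no criterion fires - 3' decay is the dominant error mode on these
instruments - and discards anything shorter than 25 bases before or after
trimming. Paired filtering drops both mates when either is discarded
(`pair_policy = "both"`), keeping files synchronised for assembly. The
whole decision procedure is checked against an O(n^2) brute-force prefix
oracle on random reads.

## Read-origin classification

The screening of reads against a labelled panel (plastid vs bacterial
references) replaces a short-read aligner with a two-stage decision that
preserves the assign/unassign contract: a read is tentatively assigned to
the reference sharing the most canonical k-mers (k = 21), and the candidate
locus - taken from the modal match diagonal - must then be confirmed by a
banded semi-global edit distance of at most 5, echoing the edit-distance
setting of the original alignment. Ties break by category (plastid first)
then lexical reference id, so results are order-independent and
deterministic. `min_hit_fraction` (default 0.5) controls stringency for
reporting; recruitment (below) lowers it to 0.05 because there the
edit-distance check supplies precision and recall is what matters.

## Assembly

* **Recruitment**: a pair is recruited when either mate is assigned to any
  reference under the classifier contract. With error-free same-species
  reads recall is 100%; at 2% divergence pair-level recall stays above
  95%, and bacterial reads essentially never pass the edit-distance check.
* **de Bruijn assembly**: contigs are unitigs (non-branching paths) of the
  canonical k-mer graph; k-mers are 2-bit packed in 128-bit words so the
  long k values plastome sweeps use (up to 63 here) are supported. With
  pruning enabled, short unitigs (< 3k) whose coverage falls below
  max(2.5, 0.2 x length-weighted median) are removed iteratively - these
  are sequencing-error tips and bubble arms. The absolute floor matters in
  the first round, when error arms still dominate the unitig set and drag
  the median down.
* **k selection**: the k whose *additive* contig length is closest to the
  expected plastome size wins; the stated rule has no printed tolerance, so
  it is implemented as the argmin of the absolute difference with ties to
  the larger k.
* **Merging** joins contigs greedily on ungapped suffix-prefix overlaps of
  at least 50 bp at 97% identity (the published merge setting). Because a
  unitig ends k-1 bases past a branch, adjacent unitigs overlap by k-1;
  this is why the sweep's larger k values (>= 51) are the ones that close
  the IR junctions.
* **Gap closing** follows the sampling design: reads are re-recruited
  against the next most closely related genome (closest first) and the pool
  reassembled, until no gap closes. Remaining micro-gaps (short stretches
  where no error-free k-mer window survived) are closed by *local
  splinting*: reads matching the two gap flanks are reassembled at
  k in {51, 41, 31} and a bridge contig that overlaps both flanks at the
  97%/50 bp thresholds is spliced in. Gaps with no read support stay open
  and are reported with their flanks - the wet-lab closure step this
  represents is out of scope by design.
* **IR resolution**: merging a quadripartite assembly yields a linear
  scaffold LSC + IRb + SSC whose two ends carry short fold-back fragments
  of the unassembled IRa copy. Those fragments are located (as
  reverse-complement self-matches of the scaffold), the full IR interval
  they bracket is taken as IRb, and the circle is completed with
  IRa = revcomp(IRb). A scaffold with fold-back evidence at only one end is
  reported as asymmetric rather than guessed at.

### The SSC orientation isomer

Plastomes occur in vivo as two "flip-flop" isomers that differ only in the
orientation of the SSC between the repeats, and short reads cannot
distinguish them: every junction k-mer set is identical because
IRa = revcomp(IRb). Assemblies therefore report one isomer arbitrarily.
`canonical_plastome()` fixes rotation (origin at LSC start), strand and SSC
orientation by taking the lexicographically smallest of the four candidate
sequences, and `plastome_equivalent()` compares canonical forms. "Exact
recovery" in the tests means equality under this equivalence, which is the
strongest statement the data can support.

## Structure

IR detection finds maximal reverse-complement self-match pairs, seeded by
exact 31-mers shared between the circle and its reverse complement, grouped
on the anti-diagonal (start1 + start2 is invariant under co-extension) and
extended to maximality. Plastome IR copies are identical, so the default
mismatch tolerance is zero; ambiguity (two non-equivalent maximal pairs) is
an error, not a silent choice. Partitioning labels the longer inter-repeat
arc LSC and the shorter SSC; equal arcs raise a tie error. Space accounting
labels every base exon > intron > intergenic (pseudogenes counted as gene
space by default, controllable by flag) and the three percentages sum to
100 exactly because they are integer base counts.

## Annotation transfer and grass features

Reference exons are located on the target by k-mer diagonal voting and
refined with a global-local alignment; hits above 80% identity and 70%
coverage become features. The thresholds leave ample margin over the <= 3%
inter-species divergence this genus complex shows while rejecting random
matches; both are configurable. IR-duplicated genes have two equally good
loci; the transfer resolves each copy to the locus colinear with its
reference copy (nearest circular offset), which keeps self-transfer an
exact identity. Protein features whose spliced sequence is no longer a
clean frame (missing start, missing in-frame terminal stop, or internal
stop) are flagged truncated; genes with no acceptable hit are listed
missing.

The grass-specific feature report measures the *rbcL*-*psaI* intergenic
arc (stop-to-start, shorter direction around the circle, hence strand
independent), calls the *rpl23*/*rpl32* remnant present when a homologous
feature lies inside that arc, and calls *accD* present/pseudo/absent by
reading-frame completeness (internal stop, missing start, or < 70% of the
reference length - any one suffices, and the reason is reported). The
*rpoC2* insertion is measured between user-supplied flank anchors because
its boundary sequences are defined in external literature and are not
shipped; without anchors the report says so instead of guessing.

## Whole-plastome comparison

Pairwise alignment is anchor-based: maximal runs of k-mers unique in both
sequences are chained colinearly (longest increasing subsequence), and
inter-anchor segments are filled by Needleman-Wunsch with affine gaps.
Equal-length inter-anchor segments - the overwhelmingly common case, a
substitution island between exact anchors - are filled ungapped, which is
the parsimonious alignment and keeps whole-genome alignment at a few
seconds. Query-gap runs are normalised to their leftmost equivalent
placement; `normalize_deletion_left()` applies the same convention to
planted truth coordinates so breakpoint comparisons are well defined even
when flanking bases repeat. The identity track (window 100, step 25 - the
published plots do not state their window, so these are config defaults)
counts query gaps as mismatch; query insertions carry no reference
coordinate and are not represented. The deletion catalogue records maximal
query-gap runs strictly longer than 40 bp within a named region, merging
runs separated by fewer than 5 reference columns so alignment jitter cannot
split one biological deletion in two.

## Phylogenomics

True multiple alignment is replaced by reference projection: each species'
pairwise alignment contributes its base at every reference column, and any
column with a gap or missing state in any taxon is excluded. This is
deterministic and matches the reference-anchored comparison framework the
rest of the package uses, at the cost of ignoring residues that align
between two queries but not to the reference - acceptable at the <= 3%
divergences involved. Tree search is exact maximum parsimony: stepwise
insertion enumerates all (2n-5)!! unrooted topologies (exhaustive, up to 12
taxa) or prunes with the monotone Fitch bound (branch-and-bound, up to 20).
All equally parsimonious trees are returned. Bootstrap supports resample
columns per replicate (multinomial over site-pattern weights, which is
exactly column resampling), re-run the search, and credit a bipartition
only when *all* co-optimal trees of the replicate contain it; supports are
percentages of replicates. A single seeded generator drives all replicate
draws, so runs reproduce bit-for-bit.

## Numerical and degenerate-input choices

* Integer PHRED medians use the lower-middle convention; thresholds are
  strict as specified ("more than three", "less than 20", "greater than
  40 bp").
* Edit-distance verification is banded (band = max_edit + 2) and
  semi-global (free segment ends), so read-vs-locus comparisons cost
  O(read x band).
* Merging models contig-end differences as substitutions only (ungapped
  overlap scoring); assembler unitigs do not end in indel errors under the
  substitution-only error model of the simulator.
* Degenerate inputs error loudly with classed conditions
  (`packing_error`, `no_ir_error`, `ambiguous_ir_error`, `tie_error`,
  `event_conflict`, `format_error`, ...), never silently coerce.
* `select_assembly` with a single candidate returns it; empty candidate
  sets are errors.

## Known limitations

* The simulator's substitution-only read errors do not model indel errors
  or instrument-specific profiles; assembler behaviour under indel-heavy
  chemistry is untested.
* Uniform intergenic filler means repeat-driven misassembly (beyond the IR
  itself) is not exercised.
* The branch-and-bound search is exact but not intended beyond ~20 taxa;
  no heuristic (NNI/SPR) search is provided.
* The reference-projection matrix discards columns absent from the
  reference, so shared insertions of the queries are invisible to the
  phylogeny.
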