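# plastomekit

Tools for assembling and comparing **plastomes** (circular chloroplast
genomes) from total-DNA shotgun sequencing reads, written for researchers
working on plastid genomics of grasses and similar taxa. The package
re-implements, as reusable and tested R functions, the complete desk side
of a plastome study:

1. **Synthetic data** — generate quadripartite plastomes
   (LSC + IRb + SSC + IRa, with IRa = revcomp(IRb)), evolve descendant
   species under a byte-replayable event log (SNPs, indels, large
   deletions, pseudogene ablations), and simulate paired-end reads with
   position-dependent PHRED qualities and bacterial contaminants — every
   pipeline stage is testable against known truth, offline.
2. **Read QC** — flag reads with >3 consecutive `N`s, >3 bases at Q≤20 or
   median Q<20; trim to the longest clean prefix; discard below 25 nt.
3. **Read-origin screening** — k-mer vote + banded edit-distance
   classification against a labelled plastid/bacterial panel.
4. **Assembly** — recruit plastome reads against reference genomes,
   de Bruijn unitig assembly over a k sweep, selection of k by additive
   contig length against the expected genome size, greedy contig merging
   at ≥97% identity over ≥50 bp, relative-guided gap closing with local
   splinting, and inverted-repeat resolution to a complete circle.
5. **Structure** — exact IR detection, LSC/IRb/SSC/IRa partition
   (LSC + SSC + 2·IR = genome length), and gene/intron/intergenic space
   accounting.
6. **Annotation** — homology transfer of gene models, cross-species
   gene-length (codon) tables, and grass-specific feature calls in the
   rbcL–psaI hot-spot (rpl23′ remnant, accD pseudogene state, rpoC2
   insertion length).
7. **Comparison** — anchor-chained whole-plastome alignment, VISTA-style
   sliding-window identity tracks, and a catalogue of deletions >40 bp.
8. **Phylogenomics** — gap-free character matrices by reference
   projection, exact Fitch maximum parsimony (exhaustive or
   branch-and-bound), and bootstrap supports.

The statistic at the core of the tree module is the Fitch length
L(T) = Σ_sites min #changes on T; searches return *all* trees attaining
min L(T), and bootstrap support of a bipartition is the percentage of
column-resampled replicates whose optimal trees all contain it.

## Worked example

```r
library(plastomekit)

# a synthetic plastome with published-scale geometry and 114 genes
g <- generate_plastome(plastome_spec(seed = 42))
g
#> plastome: 135282 bp, 136 feature(s) [LSC 79972 / SSC 12428 / IR 21441]

partition_quadripartite(g)
#> quadripartite: total 135282 = LSC 79972 + SSC 12428 + 2 x IR 21441

space_accounting(g)
#> space: gene 54.34% | intron 11.91% | intergenic 33.75%

call_grass_features(g)
#> feature_report: rbcL-psaI 1183 bp | rpl23' present | accD pseudo
#>   (incomplete reading frame) | rpoC2 insertion n/a

# simulate a 100x paired-end library and reassemble the genome from it,
# recruiting against a 1%-diverged relative
relative <- evolve_genome(g, rates = list(sub = 0.01, indel = 5e-5),
                          seed = 11)$genome
reads <- simulate_reads(g, n_pairs = round(100 * g$length / 200), seed = 7)
res <- assemble_plastome(reads, c(relative = relative$seq),
                         ks = c(41L, 51L, 61L), target_length = 135282)
res$assembly$sweep          # additive contig length per k
#>     41     51     61
#> 114001 114041 114081
plastome_equivalent(res$genome, g)
#> [1] TRUE
```

The sweep's additive lengths sit near 114 kb rather than 135 kb because the
two identical IR copies collapse into a single unitig — exactly why the IR
must be resolved explicitly: `resolve_ir()` locates the repeat from the
scaffold's fold-back ends and completes the circle, and the reconstruction
equals the truth genome up to rotation, strand and the SSC orientation
isomer (`plastome_equivalent()`).

Published bookkeeping tables (quadripartite sizes, variable-gene codon
lengths) ship as plain TSV:

```r
check_quadripartite_sizes(load_published_geometry())[, c(1, 2, 9, 11)]
#> five rows sum exactly (LSC + SSC + 2*IR == plastome size);
#> the tall fescue row is flagged inconsistent (computed 137060)
```

## Command line

```sh
Rscript inst/cli/plastomekit simulate --seed 3 --n-pairs 1000 --out-dir out/
Rscript inst/cli/plastomekit qc out/reads_1.fastq out/reads_2.fastq --out-dir out/qc
Rscript inst/cli/plastomekit structure out/genome.fasta --gff out/genome.gff3 --out-dir out/
```

Every run writes its resolved configuration as JSON next to its outputs.

## Vignette

`vignettes/plastomekit-methods.Rmd` documents the models, parameter
defaults, numerical conventions (coordinate systems, gap normalisation,
median conventions, the SSC flip-flop equivalence) and the limitations of
the synthetic world.
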