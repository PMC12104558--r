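---
title: "Methods: tracing Y chromosome dissolution with ytrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing Y chromosome dissolution with ytrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ytrace)
```

## The problem

In most mammals the male-determining Y chromosome is deeply conserved, but
the spiny rats of the genus *Tokudaia* break the rule: two of the three
species are XO in both sexes — the Y chromosome is gone as a cytological
entity — yet several essential Y-linked genes (*Ddx3y*, *Uty*, *Eif2s3y*,
*Zfy*, ...) survive, translocated onto the distal long arm of the X. The
third species retains an XY system in which both sex chromosomes have fused
with an autosome, creating neo-sex chromosomes with a large recombining
pseudoautosomal region and massively amplified Y gene copies.

`ytrace` implements, as reusable and tested components, the computational
inference stack needed to reconstruct how such a Y chromosome dissolves:

1. **Karyotype arithmetic** — fusion-only parsimony over whole-chromosome
   synteny, reconstructing the ancestral chromosome number.
2. **Rearrangement parsimony** — a signed-inversion distance engine and an
   enumeration of candidate ancestral insertion configurations for the
   Y-derived block run on the X.
3. **BASD detection** — iterative seeded discovery of the
   boundary-associated segmental duplication, the recombination substrate
   implicated in the translocations, plus flank-provenance labelling and
   the circular-intermediate (eccDNA) inference rule.
4. **Strata detection** — pseudoautosomal/stratum boundary detection from
   male heterozygous-SNP density.
5. **Repeat annotation** — repeat-unit proposal and tiling, palindrome
   calls from self-alignments.
6. **Y gene classification** — intact/pseudogene calls from
   protein-versus-genome hits and open reading frames.

A synthetic-genome generator (`sim_config()` and friends) produces inputs
with the statistical structure each stage assumes, together with
ground-truth tables, so every detector is validated by recovery tests.

## Coordinate conventions

All internal coordinates are 0-based half-open (the BED/PAF convention).
Formats that use 1-based inclusive coordinates (BLAST tabular, VCF, GFF3)
are converted at the boundary, and a minus-strand BLAST hit
(`sstart > send`) is normalised to `target_start < target_end` with an
explicit strand flag, so interval algebra is uniform everywhere.

## The rearrangement core

Arrangements are ordered lists of signed blocks (`SB1+ SB6- ...`).
`inversion_distance()` computes the exact minimal number of signed
inversions between two arrangements over the same block set, via the
extended breakpoint graph:

\[ d = (n + 1) - c + h + f \]

where \(c\) counts alternating cycles of the doubled, framed permutation,
\(h\) counts hurdles (minimal unoriented components on the framing circle,
found by run-length compression of component membership in circular
position order) and \(f\) is the fortress correction (1 when an odd number
of hurdles are all super-hurdles). Linear arrangements are capped with
fixed sentinels that never move.

Because hurdle/fortress bookkeeping is notoriously easy to get subtly
wrong, the package ships an *independent* oracle:
`bfs_distance_oracle()` runs a full breadth-first search over the reversal
graph of all \(2^n n!\) signed permutations (feasible to \(n = 7\),
645,120 states, via a vectorised BFS with base-\(2n\) state encoding). The
test suite asserts equality exhaustively for every signed permutation at
\(n \le 5\) and on hundreds of random pairs at \(n = 6, 7\). Fortresses
cannot occur at these sizes; that branch follows the published theory and
is not exercised by the oracle.

`sorting_scenario()` exhibits one optimal inversion sequence by greedy
descent: at each step it applies any inversion that lowers the distance by
one, which the theory guarantees to exist.

### Ancestral insertion parsimony

The focal X locus is modelled as four ancestral blocks `SB1..SB4` (all
`+`) that received a run of two Y-derived blocks (`SB5`, `SB6`) at one of
the three internal gaps. `enumerate_ancestral_configs()` builds all
3 loci × 2! orders × 2² orientations = 24 candidate ancestral
configurations; `score_scenarios()` computes, for each, the inversion
distance to each extant species arrangement and flags every configuration
attaining the minimal total. Ties are reported, never resolved
arbitrarily. Three modelling assumptions apply: the pre-insertion order is
fixed; the inserted blocks arrived together at one locus; duplicated
blocks (the `SB5p` partial duplicate of SB5) are excluded before distances
are computed, because the model requires unique block content.

The shipped fixture `inst/extdata/xq_locus_arrangements.tsv` encodes the
extant arrangements of the two XO species. The block *orders* are pinned
by the published boundary-duplication adjacencies (each BASD copy is named
by the block boundary it occupies, which fixes the neighbour structure);
the *orientations* are this package's reading of the cross-species
alignment, chosen — where the underlying alignment admits more than one
reading — as the encoding consistent with the reported parsimony outcome:
two co-optimal configurations, both placing the insertion between SB1 and
SB2 at a total of four inversions, with the reverse-orientation insertion
scenario costing two inversions in each lineage. Users with their own
block calls can supply their own TSV.

## Karyotype reconstruction

Whole chromosomes are windowed into non-overlapping 500 kb fragments
(`window_genome()`; the fragment name encodes chromosome and offset and
round-trips), aligned, and filtered to primary alignments strictly
exceeding 100 kb. `build_synteny_map()` lifts fragment hits back to source
coordinates and sums aligned bp over merged intervals, so overlapping hits
are never double counted.

`infer_fusions()` works under a fusion-only model: ancestral units are the
reference chromosomes; a unit corresponds to the species chromosome
carrying at least `min_fraction` (default 0.5) of its aligned bp, and a
species chromosome covering \(k\) units implies \(k - 1\) fusions. The
0.5 default is a stand-in for a manual adjudication step: it guarantees a
unique partner when one exists and surfaces ambiguous (fission-like)
signals as warnings rather than resolving them silently.
`ancestral_diploid_number()` then assembles the ancestral 2n: with one X
in the haploid set, `2 * autosomes + 2` for an XY (or restored-Y)
ancestor and `2 * autosomes + 1` for XO. For the study system: 13 extant
haploid chromosomes + 11 fusions and a restored Y give 2n = 48; the
post-Y-loss, pre-fusion ancestor gives 2n = 47.

## BASD detection

The boundary-associated segmental duplication is found by an iterative
seeded search (`iterate_basd_detection()`): align the seeds to the
genome, drop hits shorter than 500 bp (inclusive bound: exactly 500 bp is
kept), merge split hits within 3,000 bp on the same query/target/strand,
keep merged spans of at least 3,000 bp as candidates, and repeat with the
candidate sequences as new queries until the candidate set stabilises
(convergence = identical interval set after normalisation; capped at 10
iterations with a warning, since no stopping rule is inherent to the
procedure). Candidates of at least 5,000 bp become final copies, named in
coordinate order (`To-BASD001` style). Merging is partitioned by strand
to prevent chimeric palindromic merges, and operates on target
coordinates only.

Desk-scale alignment uses an internal exact k-mer anchored ungapped
aligner (`kmer_align()`, default `k = 24`, step 8): with
substitution-only divergence, homologous anchors fall on one exact
diagonal, and the anchor-spanning hit with direct base-by-base identity
is reported. Real BLASTN or minimap2 output drops into the same pipeline
via `read_blast_tab()` / `read_paf()`.

Flank provenance (`assign_flanks()`) aligns the 1.8 kb upstream and
10.8 kb downstream windows of each copy against the ancestral alpha
(upstream) and gamma (downstream) flank references — the window sizes are
the extents over which the ancestral flanks remain alignable — and labels
a side only above 500 aligned bp at ≥ 90% identity. At a two-boundary
insertion locus, `infer_mechanism()` reads the labels: an ancestral
`alpha-BASD-gamma` context split into `BASD-gamma ... alpha-BASD` is the
signature of integration of a circular intermediate (the eccDNA carries
`alpha-BASD-gamma` around the insert; homologous recombination through
the BASD ring opens it so that gamma leads and alpha trails), whereas the
unsplit order indicates direct insertion; anything else is undetermined.

`cluster_by_identity()` provides a deterministic single-linkage identity
clustering of copies as a lightweight stand-in for a maximum-likelihood
tree, which is out of scope here.

## Strata detection

Heterozygous-SNP candidates are filtered to single-nucleotide
substitutions with allele fraction in [0.25, 0.75] and depth within
[mode/2, 1.5 × mode], all bounds inclusive. The depth rule is implemented
as stated (half and 1.5 times the modal depth); note that applying it to
a modal depth of 42 gives bounds (21, 63), whereas the motivating
analysis printed (21, 65) — the printed constants and the stated rule are
mutually inconsistent at the upper bound, so the package implements the
rule and accepts explicit bound overrides for data-specific cutoffs. The
depth mode is the histogram mode with ties resolved to the smallest
depth.

`windowed_density()` profiles SNPs per kb in fixed windows (default
100 kb, chosen to resolve a ~100 Mb chromosome into ~10³ windows;
configurable); windows overlapping a mask (heterochromatin) are excluded.
`detect_boundary()` fits a single change-point, mean-shift model by least
squares over the unmasked window densities. The change-point method is
this package's choice — the boundary in the motivating analysis was
located descriptively — and a call is valid only when the post-boundary
mean exceeds the pre-boundary mean by a factor (default 3), so a
uniformly quiet track (a female X, or any non-differentiated chromosome)
yields an explicit no-boundary result rather than an arbitrary split.
`subdivide_stratum()` splits the differentiated stratum at an inversion
interval into S1a/S1b and reports per-segment means, with no statistical
claim attached.

## Repeats and palindromes

`propose_unit()` automates reading a repeat period off a self dot-plot:
candidate periods are the modal off-diagonal offsets of plus-strand
self-hits (trivial diagonal removed), clustered with a jitter tolerance
scaled by the smallest offset so that consecutive period multiples never
merge, ranked by aligned-bp support; the candidate unit is the
period-length window of maximal hit coverage. The final unit choice stays
with the user, mirroring the manual step it replaces. `tile_unit()`
counts copies by walking unit-versus-region hits in target order,
starting a new copy whenever the query coordinate restarts or a gap
exceeds half a unit; clusters covering at least half the unit count as
full copies and the rest are reported separately as partials (the partial
cutoff is a documented default, not a claim about the published counts).
`detect_palindromes()` reports minus-strand self-hits with arms of at
least 10 kb at ≥ 90% identity, arms non-overlapping, mirrored duplicates
collapsed and overlapping calls merged to maximal extent.

## Y gene classification

`find_loci()` clusters protein-versus-genome hits per gene and
chromosome (hits within twice the 10 kb pad join one locus), computes hit
coverage as the union of aligned query intervals over the query length,
and keeps loci strictly above 50% coverage, padded ±10 kb and clipped —
genes with no retained locus are absent. `find_orfs()` scans all six
frames; an ORF runs from an ATG to its nearest in-frame stop with no
internal stop, and any codon containing N breaks ORFs spanning it.
`classify_gene()` calls a locus intact when its longest ORF covers at
least 80% of the reference protein (in amino acids) and pseudogene
otherwise; the threshold asymmetry (> 50% coverage, ≥ 80% ORF) follows
the stated decision rules, and the 80% rule is applied uniformly across
genes. A single mid-CDS frameshift truncates the longest ORF to roughly
half the query and is therefore always called pseudo. `copy_table()`
aggregates calls into a gene × region × {intact, pseudo} table by locus
midpoint. Splice-aware alignment is not re-implemented; tabular hits are
the interface, and exon-chain reconstruction is out of scope.

## The synthetic-data generator

`sim_config()` fixes the study conditions the tests run under:

* 24 ancestral haploid chromosomes (23 autosomes + X) with fusion plans
  of 11, 1 and 2 fusions — giving extant haploid counts of 13, 23 and 22
  and an ancestral 2n of 48;
* focal locus `SB1+ SB2+ SB3+ SB4+` with `SB6- SB5-` inserted between
  SB1 and SB2 and two random inversions per derived lineage;
* 6 kb BASD copies at 98% pairwise identity planted at block boundaries,
  with gamma/alpha flank replicas at the insertion boundaries in the
  split (circular-intermediate) configuration;
* a 52-copy tandem repeat array and a 30 kb-arm palindrome (desk-scale
  stand-ins for the published 542 kb unit and ~300 kb inverted
  duplication);
* gene copies embedded in the Y-derived SB5 block, intact or carrying a
  1 bp mid-CDS frameshift;
* a SNP track stepping from 0.1/kb (PAR) to 5/kb (stratum) at a 5 Mb
  boundary on a 10 Mb chromosome, depth mode 42, with 10% of records
  deliberately violating the filters.

Mutations controlling planted identity are substitutions only, keeping
the identity arithmetic closed-form: each duplication replica is mutated
at the per-base rate \(r\) solving
\(2r(1-r) + \tfrac{2}{3}r^2 = 1 - \mathrm{identity}\), so the *pairwise*
identity of two replicas is the configured value in expectation
(binomially distributed around it). Emitted alignment tables are computed
from truth coordinates, not by running an aligner, so detector tests are
self-contained; the internal k-mer aligner is nevertheless exercised
end-to-end by the BASD recovery tests, which align real planted sequence.
Every generator draws from a single PRNG stream seeded from the config,
so identical configs give byte-identical outputs.

What the generator does **not** emulate — and what passing recovery tests
therefore do not establish about real data: indel and structural
divergence between duplication copies (an indel rate option exists but
defaults to 0), interspersed repeat families and low-complexity sequence
(null genomes are base-shuffled), read-level artefacts upstream of the
VCF, GC and mutation-rate heterogeneity, and genome-scale copy numbers
(the published per-species counts of BASDs, repeat copies and gene copies
at full chromosome scale require the deposited assemblies and are out of
desk-scale reach by design).

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk run: exhaustive
distance verification to \(n = 5\) plus 200 random pairs at \(n = 6, 7\);
20 duplication-recovery genomes of ~0.1–0.15 Mb with 2–8 planted copies;
100 SNP tracks of 4 Mb at a 20× density step; 52-copy repeat arrays.
Degenerate inputs are handled explicitly: empty hit tables propagate as
empty results, zero-length regions and overlapping count regions are
errors, flat density tracks return no boundary, and ties (depth-mode,
scenario totals, synteny orientation) resolve by documented deterministic
rules (smallest value, report-all, `"."`).

## Known limitations

* The inversion-only distance ignores duplications; duplicated blocks
  must be excluded before scoring, which discards part of the signal.
* The internal aligner assumes substitution-only divergence; indel-rich
  homology needs external alignments fed through the readers.
* The fusion-only karyotype model reports fissions as violations instead
  of modelling them.
* Single change-point detection cannot represent multiple strata
  boundaries; callers needing more segments should run it hierarchically.
* `find_orfs()` reports single-exon ORFs only; spliced genes are handled
  upstream by the (external) spliced aligner producing the hit table.
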