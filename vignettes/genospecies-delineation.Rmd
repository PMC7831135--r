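---
title: "Delineating genospecies in bacterial species complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating genospecies in bacterial species complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genodelim)
```

# The problem

Named bacterial species such as *Rhizobium leguminosarum* frequently turn
out to be species *complexes*: collections of discrete genomic clusters
("genospecies") that satisfy any genome-based species definition
individually, yet share one Linnaean name. `genodelim` implements the full
analysis used to dissect such a complex from genome assemblies:

1. **Fragment-based ANI.** Average nucleotide identity between two
   assemblies, computed fastANI-style: the query is cut into 3000-nt
   fragments, each fragment is mapped to the reference by shared 16-mers
   and aligned within a 32-column band, and ANI is the mean identity of
   mapped fragments. ANI is undefined when fewer than 20% of fragments map.
2. **Genospecies delineation.** Single-linkage clustering of the
   symmetrized ANI matrix at a 96% threshold, followed by a compactness
   refinement (complete-linkage subclusters, a 98% compactness criterion,
   tree-monophyly checks, and tree-guided re-assignment of "bridge"
   strains), per-cluster boundary-gap detection, medoid representatives,
   and unplaced singletons as a first-class outcome.
3. **Core-gene phylogeny.** Translated search of reference core proteins
   against each genome, extension of hits to the expected gene length,
   reference-anchored alignment, concatenation, Jukes–Cantor distances and
   a neighbor-joining tree rooted on an outgroup, with gene-resampling
   bootstrap and a split-half (2 × 60 genes) robustness check.
4. **Compartments.** Scaffolds are classified chromosomal if they carry at
   least one (optionally at least five) best-hits of chromosomal marker
   genes; ANI is then computed per compartment.
5. **Accessory genome.** ORF calling, reciprocal-best-hit orthogroups with
   copy-number filters, and the normalized gene sharing index
   ½(|S|/|A| + |S|/|B|), related to ANI by rank correlation.
6. **Marker typing.** 16S extraction and variant profiling against a
   standard sequence (including intervening-sequence detection), symbiovar
   assignment from NodD/A/B/C best matches, and housekeeping-amplicon
   classification against labeled reference alleles.

Every stage can be exercised end-to-end on a synthetic species complex
with complete ground truth (`simulateComplex()`).

# The synthetic species complex

The simulator emulates the structure of a rhizobial species complex at
desk scale. One random ancestor genome is built: a chromosome carrying
core genes, chromosomal marker genes, three housekeeping genes with
planted primer sites (informative interiors of 534, 719 and 602 nt for
*atpD*, *gyrB*, *recA*), and one 16S copy; plus conserved plasmid
backbones and an accessory plasmid carrying genospecies-specific accessory
genes and, for symbiotic strains, a NodDABC cassette.

Lineages diverge under a star topology with a uniform substitution model
(each site substituted with probability *d*, uniformly to one of the three
other bases; no indels by default, an optional small-indel mode exists for
robustness tests). **Divergence parameters are pairwise**: two strains
"at divergence *d*" differ at a fraction ≈ *d* of sites, so their expected
ANI is 100·(1 − *d*). Branches therefore carry *d*/2. Defaults:

| parameter | default | meaning |
|---|---|---|
| `within_gs_divergence` | 0.005–0.02 | within-genospecies pairwise divergence (ANI 98–99.5%) |
| `between_gs_divergence` | 0.045–0.08 | between-genospecies divergence (ANI 92–95.5%) |
| `outgroup_divergence` | 0.085 | outgroup vs ingroup (ANI ≈ 91.5%, the sister-species range) |
| `plasmid_rate_multiplier` | 1.5 | plasmids diverge faster than the chromosome |
| `chrom_len` | 200 kb | desk-scale stand-in for a ~5 Mb chromosome |
| `n_core_genes` | 120 | universal core-gene set size |
| `n_chrom_markers` | 40 | stand-in for the ~3215-gene chromosomal marker list |

Accessory genes live in per-genospecies pools; a strain retains a pool
gene with probability `accessory_retain_prob · exp(−decay · divergence)`,
which produces the higher within- than between-genospecies sharing and the
positive sharing–ANI correlation seen in real complexes. Housekeeping
introgression events overwrite a recipient's allele with another
genospecies' ancestral allele, so single-gene classification fails exactly
there while multi-gene classification recovers. Scaffolds are shuffled and
renamed on emission so compartment labels cannot be inferred from names.

**What the simulator does not emulate:** recombination tracts other than
whole-gene introgression, rearrangements, realistic codon usage or GC
skew, contamination, and assembly fragmentation/error. Passing tests on
simulations therefore validate the *algorithms* under the stated model,
not robustness to every artifact of real assemblies — real-data users
should treat the marker lists, core proteins and primer sequences as
configurable inputs and inspect the unplaced/ambiguous outcomes.

# Numerical and design choices

**Alignment scoring.** Nucleotide: match +1, mismatch −1, gap open 5,
extend 2 (a gap of length L costs open + L·extend). Protein: BLOSUM62,
gap open 11, extend 1. IUPAC ambiguity codes score as mismatches and never
seed. Local traceback ties break diagonal > up > left, and equal-scoring
local alignments resolve to the longest (traceback continues through
zero-score cells reachable by a genuine path), so all results are
deterministic.

**Search.** Translated search seeds on exact amino-acid 5-mers across all
six frames; nucleotide search on exact 11-mers on both strands. Seeds
cluster by diagonal; each cluster's window is aligned with full
Smith–Waterman. E-values are Karlin–Altschul,
`E = K · m · n · exp(−λS)` with database length = total scaffold length ×
2 strands; protein λ = 0.267, K = 0.041 (gapped BLOSUM62), nucleotide
λ = ln 3 (the exact ungapped solution for +1/−1 at uniform base
composition), K = 0.333. The cutoffs in use (10⁻¹⁰ for gene finding,
10⁻⁵ for nod genes) are generous, so results are insensitive to the exact
calibration; random-sequence property tests confirm no spurious passes.
Best hits are chosen by (score, E-value, lexicographic scaffold id,
smaller start). Hit extension splits the length deficit symmetrically,
truncates at contig ends and does not re-add a truncation deficit at the
other end.

**Fragment ANI.** Mapping accepts a reference window only with ≥ 5 shared
16-mers (suppressing spurious mappings between unrelated sequences) *and*
alignment identity ≥ 0.8 — the analogue of the Mashmap mapping-identity
floor in fastANI. Without the identity floor, a single chimeric fragment
spanning strain-variable accessory cargo can dominate a desk-scale ANI
estimate (dozens of fragments per genome rather than thousands). Identity
is matches / fragment length over a banded (±32) semi-global alignment of
the fragment in the chosen window, so unaligned fragment ends count
against identity. Directed values are symmetrized by the mean of the
defined directions. Self-ANI is exactly 100; calibration on substitution-
only pairs is within 0.5 points of 100(1 − *d*), and fragment ANI agrees
with whole-genome banded global alignment within 1 point on ≤ 20 kb
genomes.

**Delineation.** Initial clusters are single-linkage components at 96%
ANI (undefined entries contribute no edge) — single linkage reproduces
the chaining behaviour that makes bridge strains a problem worth
refining. Refinement then works per component: complete-linkage
subclusters cut at the species threshold; a split is accepted only when
at least one subcluster is compact (all pairwise ANI ≥ 98%) and every
subcluster is monophyletic in the core-gene tree; strains still bridging
above-threshold across subclusters are re-assigned to the subcluster of
their closest tree neighbour (smallest cophenetic distance). Strains left
alone by a split, and singleton components, are unplaced — mirroring the
handful of unique strains real complexes contain. The boundary gap for
each genospecies is the largest empty interval between consecutive sorted
ANI values to the representative that intersects the window [94.5, 97.5];
the representative is the medoid (maximum mean ANI to the rest, ties by
lexicographic id). The refinement rule is one consistent formalization of
decisions a taxonomist would otherwise make case by case; borderline
clades can legitimately be argued either way, which is why the gap bounds
and the monophyly flags are part of the report.

**Phylogeny.** Reference-anchored alignment (global alignment to the
reference gene, insertions relative to the reference dropped) replaces a
full multiple-sequence alignment: core genes within a complex are ≥ ~92%
identical, so projection loss is negligible, and the procedure is fully
deterministic. Distances are Jukes–Cantor, `d = −¾ ln(1 − 4p/3)`, over
columns where both rows are ungapped (saturation p ≥ 0.75 is an error,
not a silent NaN). Trees are canonical neighbor joining with negative
branch lengths clamped to zero, rooted on the outgroup edge. This
distance approach replaces maximum-likelihood inference deliberately: at
the divergences involved (p ≤ ~0.1) NJ on concatenated data recovers the
same monophyly structure, and the package tests exactly that property,
including on split halves of the gene set and under gene-resampling
bootstrap (100 replicates by default).

**Orthogroups.** The ORF caller keeps the longest ORF per stop codon
(earliest in-frame ATG/GTG/TTG start, table-11 semantics, ≥ 90 codons).
Orthology is reciprocal-best-hit between genomes plus within-genome
paralog edges at ≥ 80% identity over the longer protein, single-linkage
components, then the two copy-number filters: no orthogroup with more
than two copies in any genome, and no orthogroup that is a single copy
private to a single genome. Only presence/absence feeds the sharing
index, so the simplifications relative to a full graph-clustering
orthology pipeline do not affect the downstream statistic; per-orthogroup
gene trees are out of scope.

**16S profiles.** Variants are reported in standard coordinates from a
global alignment; deletions are represented as substitutions to `"-"` so
that the profile round-trips exactly back to the observed sequence. The
intervening sequence (IVS) — an insertion of ≥ 20 nt replacing the 4-base
loop at positions 73–76 — is detected structurally, by counting observed
bases between the columns aligned to standard positions 72 and 77; this
is robust to how the aligner distributes the insert across gap runs.
Haplotyping masks substitution variants private to a single strain
(insertions are kept: the masking convention applies to point variants
only).

**Symbiovars.** Per gene (NodD/A/B/C), the vote is the symbiovar of the
best-scoring reference allele; the call requires at least two genes
present and unanimous votes; a genome with no nod genes *or only NodA* is
non-nodulating (NodA-like sequences occur outside functional symbiosis
cassettes); disagreeing votes yield `"conflict"` rather than a guess.

**Amplicon classification.** Nearest reference allele by global-alignment
identity; a call needs ≥ 98% identity and agreement of all references
within 0.5 points of the best; otherwise `"ambiguous"` (top references
disagree) or `"novel"` (nothing close). The multi-gene wrapper takes a
majority vote across informative genes (ties → ambiguous); strict
intersection would return empty whenever a single allele is introgressed,
which is precisely the case multi-gene typing exists to rescue.

# Problem sizes

The test suite and the acceptance script run the whole pipeline on
simulations sized for a desk machine, chosen once as the smallest scales
at which each property is meaningfully exercised: 200 kb chromosomes for
ANI calibration (≈ 66 fragments per genome), 18 kb toy genomes for the
whole-genome alignment oracle, 5 genospecies × 6 strains + 2 isolates
(+ outgroup) for recovery and compartments, 5 × 2 strains with the full
120-gene set for the split-half phylogeny, 3 × 3 strains with 10-gene
accessory pools for sharing, and 2 × 4 strains with two introgression
events for marker typing. Defaults in `simConfig()` are the same
conditions; `chrom_len` can be raised to multi-megabase scale when
runtime is no concern.

# Known limitations

* ANI values agree with fastANI only to within the tolerances above; this
  is not a byte-compatible reimplementation (no MinHash approximation, no
  identical mapping filter).
* The search engine has no HSP chaining across large insertions and no
  low-complexity masking; bacterial genes are assumed contiguous.
* Compartment classification knows only chromosomal/plasmid; chromids are
  grouped with plasmids, and the marker-gene list is an input, not a
  shipped resource.
* The refinement rule is deterministic but not guaranteed to match expert
  judgment on every borderline clade; inspect gap bounds, monophyly flags
  and unplaced strains before naming anything.
* Amplicon informative lengths depend on the primer definitions supplied;
  the shipped values are the simulator's planted primers.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs every stage on
freshly simulated data and writes the quantities it measures (calibration
error, recovery ARI, unplaced counts, monophyly fractions, compartment
accuracy, sharing statistics, marker accuracies) as JSON. The README
shows a worked example with the output of an actual run.
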