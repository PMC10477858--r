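---
title: "Methods: community-scale phage DNA-methylome analysis"
author: "phageMethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-scale phage DNA-methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageMethylome)
```

# Scope and model

This package analyses the DNA methylome of a phage community from
single-molecule base-modification calls. The biological model is the
restriction–modification (RM) arms race: bacterial RM systems cleave
unmethylated recognition motifs, so phages whose genomes are methylated at
the right motifs — often by phage-encoded DNA methyltransferases (MTases)
acquired from their hosts — survive better. Three consequences structure
the analysis: methylation should be pervasive and motif-driven; methylation
density should correlate with phage success (prevalence) once technical
covariates are controlled; and phage MTases should be close homologs of
host MTases, making them usable for host prediction.

The package implements the analysis stages as pure functions over standard
Bioconductor containers (`DNAStringSet`, `AAStringSet`, `GRanges`) and
validates them end to end on a synthetic community with planted ground
truth. Coordinates are 1-based inclusive throughout, the native convention
of `GRanges` and GFF3, so file I/O performs no coordinate shifts.

# Viral recognition, filtering and lifestyles

`classifyViral()` encodes a voting rule over per-contig tool evidence. The
comparators are deliberately asymmetric — VirSorter passes at `>= 0.7`
while VirFinder and PPR-Meta require strict `> 0.6` and `> 0.7` — and are
applied exactly as stated; the boundary behaviour is pinned by tests. The
fifth criterion (phage-orthologous-group ORFs) requires both an absolute
minimum of three hits and a density of two per 10 kb, computed as
`hits / (length / 10000)` with real-valued length rather than a floored
window count. Missing tool scores count as criterion-failed, never as
errors, because real pipelines have partial evidence. A circular contig is
viral outright; otherwise two criteria vote a virus, and a single criterion
suffices only with CheckV completeness at or above 90%.

Virulence scores partition `[0, 1]` into half-open lifestyle bins
`[0, 0.3]`, `(0.3, 0.5]`, `(0.5, 0.7]`, `(0.7, 1]`. Only the outer
comparators ("<= 0.3", "> 0.7") are stated explicitly in the convention
this follows; the interior edges were chosen half-open so that the four
bins tile the interval, which places a score of exactly 0.5 in the
uncertain-temperate bin. The crAssphage rule demands length > 70 kb plus
either a polymerase/terminase protein hit at e < 1e-10 or >= 95% nucleotide
identity over >= 80% of the contig; Gubaphage genera are assigned by the
best terminase hit at e < 1e-5, with e-value ties broken by the
lexicographically smaller genus (the rule is silent on ties, so a
deterministic convention was fixed).

# Methylation density

Density is the count of distinct methylated bases of one type divided by
the count of target bases of both strands: for m6A the denominator is
forward A plus forward T (every adenine of the duplex), for m4C the
cytosines. Base-modification calls are strand-specific, so the
denominator must also count both strands; sites are deduplicated on
(genome, position, strand, type), which merges repeated observations of
the same site across samples. A site whose underlying base contradicts its
type (an m6A call on a C) is a hard error, not a warning — it indicates
corrupted coordinates.

Coding/non-coding splits classify a position as coding when it lies in the
union of CDS intervals; the genome-wide density is then exactly the
base-count-weighted mean of the two region densities, an identity the
tests assert to 1e-12. Per-CDS summaries report the fraction of CDSs with
at least one site and a per-CDS modified-base ratio. The ratio's
denominator is ambiguous in the convention this mirrors ("modified
bases/genome length per CDS"); the default uses each CDS's own length,
with `perGenomeLength = TRUE` for the literal genome-length variant.

Prevalence counts samples with RPKM at or above 0.5 (a value exactly at
the threshold is present), and the association between prevalence and
density is a first-order partial Pearson correlation controlling for
sequencing depth, computed from the closed-form recursion and equal (to
1e-10 in tests) to the Pearson correlation of the OLS residuals of each
variable on depth. The depth covariate is the accumulated per-genome
coverage implied by the read counts, since the raw signal scales with how
often a genome was sequenced. P-values are two-sided.

# Degenerate motif algebra

Motifs are IUPAC patterns with a methylated-position index. The overlap
relation is possibility subsumption: pattern X is overlapped by pattern Y
when some window of the longer (more specific) pattern consists of
position-wise subsets of the shorter (more general) one — `AKCTCG` is
overlapped by `BCNC` via its window `KCTC`. This direction (windows of the
longer subsumed by the shorter) is the only one consistent with that
example. Equal-length patterns are tested in both directions, mutual
subsumption meaning equivalence. Dereplication removes subsumed motifs of
the same modification type, iterating to a fixed point, keeping the more
general (covering) motif, and breaking equivalence ties by the
lexicographically smaller pattern; the result never contains two
overlapping motifs of the same type and the operation is idempotent.
Reverse-complement matching is available behind a flag but off by
default. Scanning uses `Biostrings::matchPattern(fixed = "subject")`, so
degenerate codes in the pattern are base sets while the genome is literal;
tests check it against a literal-expansion oracle. Support filtering
retains motifs found in at least `minGenomes` genomes (the community-scale
default is 100), and m4C/m6A union accounting counts shared motifs on
pattern identity alone, since a shared motif is the same sequence with a
different methylated base.

# MTase annotation, enrichment and clustering

MTases are annotated from conserved-domain hits against an
eleven-accession whitelist at e <= 1e-5. Orphan/non-orphan status is
inherited from each protein's best reference hit — lowest e-value, ties
broken by highest SimScore then lexicographic subject id — and enrichment
of non-orphans is tested with the one-sided hypergeometric upper tail
`P(X >= k)` (population N with K non-orphans, draw n, observe k) and a
Pearson chi-square on the 2x2 table without continuity correction. The
hypergeometric population is passed explicitly by the caller because the
natural choice (reference catalogue alone versus catalogue plus sample) is
genuinely ambiguous; the package does not assert either.

Protein similarity uses Smith–Waterman local alignment with BLOSUM62 and
affine gaps (open 11, extend 1), the conventional protein-search scoring.
Identity is matches over alignment columns, query coverage the aligned
query span over query length, and SimScore their product over 100. The
all-against-all search pre-screens pairs by shared 4-mer seeds (at least
three distinct shared k-mers), as seeded homology search tools do, so
unrelated random pairs produce no edge; no e-value is computed for
in-package alignments, and the graph filter therefore applies the e-value
cutoff only to externally supplied edge tables that carry one. Edges need
query coverage strictly above 75%; the graph is symmetrised by the maximum
SimScore of the two directions.

Markov clustering is implemented in-package as the classical dense
iteration: column-stochastic matrix with self-loops (each node's loop
weight equals its maximum incident weight, a standard regularisation that
guarantees aperiodicity), expansion by squaring, inflation by entry-wise
power 2 with column renormalisation, pruning of entries below 1e-5, to a
1e-8 fixed point with a 100-iteration cap (non-convergence returns the
current interpretation with a warning). Clusters are connected components
of the limit support; every node is assigned and isolated nodes become
singletons. Inflation 2 is the cited implementation's documented default.
Tests check the iteration against an independently hand-coded dense-matrix
oracle and assert column stochasticity to 1e-9 at every iteration.

# Host prediction

The prediction feature between a phage and a candidate host is the maximum
SimScore over their MTase-protein pairs (the aggregation is not specified
by the convention this follows; the maximum is the natural single-feature
choice and is what the AUC calibration uses). Assignment is rule-based:
each phage protein keeps only its highest-SimScore edge, and a host
qualifies when at least two distinct phage proteins hit it with SimScore
strictly above 90 ("higher than 90%" read as strict). All qualifying hosts
are kept; host multiplicity is summarised by the LCA host range
(single host: species; multiple hosts: the deepest rank on which all
agree). Negative pairs for AUC are sampled uniformly from non-gold pairs,
excluding hosts of the same species as a phage's known host to avoid label
noise. Precision counts each assignment once and is evaluated at species
and genus rank; genus precision can never be below species precision.

# The synthetic community generator

The generator exists so that every stage can be validated against known
truth without any external database. Its defaults are the study
conditions: 50 phages and 50 bacteria, 104 samples, phage genomes of
10–30 kb at 50% GC, lifestyle proportions 13.7/59.6/18.6/8.1%
(temperate to virulent), shared-MTase identity 0.95 versus decoy identity
0.70, two shared MTases per linked phage, 60% of phages linked to a host,
and a prevalence–density coupling of 0.8.

Planted methylation is drawn only from occurrences of the configured
motifs (six short RM-type recognition motifs by default: GATC, GANTC,
CATG for m6A; CCWGG, GCGC, CCGG for m4C), with the methylated base at the
motif's methylated index — faithful to the mechanism, where sites arise
from MTase sequence specificity. Per-lifestyle density targets
(m6A falling and m4C rising with virulence, 0.004–0.010) were set an order
of magnitude below the motif-occurrence ceiling of a random 10–30 kb
genome, so targets are achievable and realised densities land within a few
percent of target (rounding error only); the generative trend directions
mirror the qualitative pattern the analysis is meant to detect, while the
effect sizes are free configuration, not claims.

Protein evolution is substitution-only (no indels), which makes identity
exactly controllable and matches the identity-regime analyses the homology
stage supports. Host links give each linked phage two MTases evolved from
its host's at 95% identity, and plant decoy copies at 70% identity in
non-host bacteria, so correct prediction requires the SimScore threshold
to separate the two regimes rather than mere edge existence.

Abundance uses a monotone logit link: each genome's presence probability
is `plogis(qlogis(0.3) + 4 * coupling * z)` with `z` the z-scored planted
density; present genomes get log-normal RPKM levels converted to integer
counts given the sample library size, and the emitted RPKM matrix is
recomputed exactly from counts. Only the correlation's existence and sign
are modelled — no generative law for it is claimed by the conventions this
follows, so the logit link is the package's own minimal choice. The depth
covariate derives from the counts, making it a genuine confounder that the
partial correlation must control for.

What the generator does *not* emulate: realistic genome architecture or
codon usage, read-level noise (no FASTQ), partial/heterogeneous
methylation within a population, alignment errors, or indel evolution.
Passing recovery tests therefore demonstrates the correctness of the
statistical machinery under its stated assumptions, not robustness to the
messiness of real metagenomes.

# Numerical choices and problem sizes

Degenerate cases are handled explicitly: empty denominators return density
0 with a warning; unreachable density targets warn and emit the maximum
achievable set; a constant control variable reduces the partial
correlation to the plain Pearson correlation, while a control collinear
with a variable of interest is an error; equal proportions short-circuit
the chi-square to statistic 0, p 1 (avoiding 0/0 in degenerate tables);
and rarefaction at fraction 1 returns the exact unique-site count without
resampling.

All randomness flows from a single integer seed through stage-specific
sub-seeds, so a config plus seed reproduces byte-identical artifacts and
reports; this is asserted by checksum tests. The validation suite
exercises 10-genome communities for unit-level checks and sweeps ten
seeds of the full 50-phage/50-bacterium default community for parameter
recovery (host-prediction precision/recall, density recovery, partial-
correlation sign); exhaustive oracles run at small sizes (all
hypergeometric cases with population at most 30, thousand-pair motif
oracle sweeps, tiny rarefaction enumerations). These sizes were chosen as
the smallest at which the recovery claims are meaningful; all scale
linearly if larger runs are wanted.

# Known limitations

- m5C is out of scope (not reliably callable by the underlying chemistry
  in prokaryotic/viral contexts), as is calling modifications from raw
  kinetics.
- The in-package aligner reports no e-value; statistical significance of
  an edge is implied by the seeded search plus coverage filter rather than
  an extreme-value model. Externally computed edge tables with e-values
  are accepted wherever edges are consumed.
- `lcaHostRange` resolves ranks down to family against the generated
  three-level taxonomy; hosts disagreeing at family collapse to the root
  rank rather than to intermediate ranks (order/class/phylum) that the
  generator does not populate.
- Whether the "two per 10 kb" ORF density counts distinct ORFs or total
  hits is ambiguous in its source; it is implemented as distinct ORFs with
  hits, and the evidence schema carries a single count accordingly.
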