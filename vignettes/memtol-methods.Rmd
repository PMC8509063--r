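---
title: "Methods: pooled-screen statistics and packing analysis in memtol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-screen statistics and packing analysis in memtol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtol)
```

This vignette is the package's account of the science it implements: the
models and procedures, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design choices made where the
methodology was genuinely open.

## The screening model

The system being modelled is a phenotype-pooled saturation-mutagenesis
screen of a toxin: cells expressing an active toxin die under induction,
so a *wild-type phenotype* means no growth (the mutation is tolerated by
the toxin) and a *mutant phenotype* means growth (loss of function). Note
the inversion — "wild-type phenotype" labels the pool in which *tolerated*
mutations accumulate. Colonies from the two phenotype classes are pooled
separately and the mutagenised open reading frame is amplicon-sequenced,
so each read covers the full mutagenised region and carries a pool label.

For a mutation $i$ observed $WT_i$ times in the wild-type-phenotype pool
and $MUT_i$ times in the mutant-phenotype pool,

$$F(mut_i) = 100 \cdot \frac{WT_i - MUT_i}{WT_i + MUT_i} \in [-100, 100].$$

With this orientation $F > 0$ means enrichment with the wild-type
(toxin-active) phenotype, i.e. a tolerated mutation, and $F < 0$ a
deleterious one. Variants seen in both pools at comparable frequency are
*incorrect sequence–phenotype assignments* (ISPAs) — artifacts of
mis-pooling, chimeric reads or sequencing error — and are excluded by the
band $|F| \le e$, where $e$ is the experimental error rate in percent.
The default $e = 4$ is the rate used in the HokC screen; it is a property
of the experiment, not of the statistic, and is configurable everywhere.

Two classification tiers are kept deliberately separate:

* **substitution-level** statistics aggregate counts over every genotype
  containing a given single substitution; deleterious calls and
  per-position summaries come from this tier;
* **genotype-level** statistics classify whole variants; compensatory
  detection — multi-substitution genotypes classified tolerated that
  contain an individually deleterious substitution — comes from this tier.

A position is *critical* when its deleterious substitutions strictly
outnumber its tolerated ones (ratio > 1; a tie is not critical).
Reported percentages round half away from zero to match conventional
integer reporting; full-precision values are retained in the tables.

Two knobs guard data quality. `max_pos` removes observations mutated
beyond the analysed segment (strictly greater than the bound, so the
boundary residue itself is retained). `min_total` drops records whose
total count is below a floor; with a designed depth of 500 reads per
variant, the analyses in this package use `min_total = 100` (20% of
design depth). The rationale: genuine variants arrive at totals near the
design depth, while substitution artifacts created by sequencing errors
on *other* variants' reads arrive at totals two orders of magnitude lower
(tens, at a 0.5% per-base error), so any floor in the wide gap between
them gives the same answer. Reads whose translation hits a stop codon
inside the analysed span are counted separately as nonsense variants and
never enter missense statistics; with an SNS library no stop codon is
designed, so nonsense reads indicate sequencing error. Residues read as
`X` (ambiguous bases) are never called as substitutions.

## Library design arithmetic

A degenerate codon scheme fixes a nucleotide set per codon position. SNS
(S = G/C, N = any) yields $2 \times 4 \times 2 = 16$ codons encoding 10
amino acids — L, P, H, Q, R, V, A, D, E, G — and no stop codon, trading
coverage of the amino-acid alphabet for a screenable library size while
keeping physicochemical diversity. A region of $L$ residues at $k$ amino
acids per position expects $Lk$ single variants and $k^L$ combinations
(3 residues at 10 amino acids: 30 singles, 1000 combinations). The
default layout tiles the transmembrane segment of the HokC short ORF in
seven regions over residues 2–24 (region II = 7–9, region VI = 19–21).
Variant counts are always computed from the configured regions rather
than fixed constants, because the published "expected" total (240) does
not factor as regions × alphabet under any configuration of this layout
(23 positions × 10 = 230); `summarize_screen()` therefore takes the
expected, detected and deleterious counts as explicit inputs.

## Alignment analyses

Conservation is measured against a designated reference row: the score of
a reference position is the fraction of rows whose residue at that column
equals the reference residue. A gap never matches; by default gapped rows
stay in the denominator (the simplest reading of "sequences that maintain
the same residue"), and `gap_policy = "exclude"` removes them instead.
Columns where the reference itself is gapped have no reference coordinate
and are skipped by every reference-coordinate analysis.

A homolog is a *compensated sequence* when its substitution set contains
at least one experimentally deleterious single **and** at least two
substitutions in total — a multiple mutation harbouring a loss-of-function
mutation, the sequence-level signature of compensation. Matching is by
exact substitution by default (same reference residue, position and
alternate); position-level matching is available because family alignments
rarely reproduce the exact alternate residue of a screen.

The **correlated mutation index** conditions on structure: only residue
pairs in contact (any-atom distance < 5 Å) are examined. For each of the
400 ordered amino-acid pair types, `observed` counts the contacting pairs
of that reference type and `mutated` counts (row, pair) events in which
both positions carry non-gap residues differing from the reference. The
default index is `mutated / observed`, the convention of the worked
example in which 30 Ala–Ala contacts mutated 15 times give 50%. This
quantity is a *rate of events per pair* and can exceed 1 in deep
alignments; the alternative `normalizer = "rows"` divides additionally by
the number of rows and is bounded by 1. Both are reported because the
event unit ("mutated 15 times in the MSA") is ambiguous in the source
convention; the two normalisers induce identical rankings of pair types,
so recovery analyses are unaffected by the choice. The unordered 210-type
view is available by symmetrisation.

## Contact graphs and packing

Residues $i \ne j$ are in contact when their closest atom pair is
*strictly* closer than the cutoff (default 5 Å, the conventional
heavy-atom contact distance). All atoms present are used; deposited
crystal structures usually lack hydrogens, and the reader drops them by
default so that files with and without hydrogens are treated alike.
Sequence-adjacent pairs are genuine contacts and are included; a minimum
sequence separation is available for analyses that want to ignore the
backbone. Each chain is processed independently, with residues re-indexed
1..n in file order and the first alternate-location conformer taken.

Packing is profiled two ways. Globally, the *size* (residue count) versus
*order* (contact count) of many chains is fitted by ordinary least
squares; under constant packing density the points fall on a line whose
slope is the number of contacts gained per added residue, and the mean of
$2 \cdot \mathrm{order} / \mathrm{size}$ (mean contacts per residue) is
reported alongside because the two coincide only asymptotically. Locally,
maximal cliques — fully connected residue sets not contained in any larger
one — of sizes 3, 4 and 5 are counted via igraph's pivoting
Bron–Kerbosch enumeration; cliques larger than the profiled sizes are
counted separately so a shifted size distribution is visible rather than
silently truncated.

## Hydrophobic contact geometry

The published description of "spherical angles between contacting
hydrophobic residues" does not pin down a reference frame. The encoding
chosen here needs none: for every hydrophobic residue (default set
A, V, L, I, M, F, W, C) with at least two hydrophobic contacting
neighbours, the vector of angles subtended *at the central residue's
representative point* (side-chain centroid; Cα for glycine) by every
unordered pair of neighbours. Angles are intrinsic to the constellation,
so the encoding is exactly invariant under rigid-body motion, and each
vector is sorted descending to give a canonical form.

Two proteins are compared by the classical symmetric Hausdorff distance
between their sets of angle vectors, with vectors of unequal length
truncated to the shorter length under a Euclidean element metric
(zero-padding is available as an option). The *minimum* Hausdorff
distance searches over a one-parameter family — a global angular offset
added to every angle of the second set, representing a relative
re-orientation of the two contact geometries. The minimiser combines a
deterministic coarse scan (2° spacing) that seeds seeded simulated
annealing (Metropolis acceptance, geometric cooling, defaults
$T_0 = 100$, $\alpha = 0.95$, 500 steps) with a bracketed local
refinement; the identity offset is always evaluated, so the minimised
distance never exceeds the raw one. The one-dimensional family was chosen
over richer search spaces because the Hausdorff distance is a function of
the two sets alone — reassigning a correspondence between vectors leaves
it exactly invariant, so correspondence search is vacuous — and because a
1°-resolution grid over the offset provides an independent oracle that
bounds the annealer's quality in the test suite.

Cohort comparisons respect the usual structural-biology controls: only
pairs from the same CATH class with residue-count difference at most 20
are compared. A pair has *identical orientation* when its minimised
distance is at or below a tolerance, default 1°; no tolerance is canonical
for this notion, so the default is deliberately strict and the per-class
tables report full distance summaries (median, min, max) alongside the
identical fraction.

## What the generators emulate — and what they do not

**Read pools** (`screen_truth()` / `simulate_read_pools()`). The defaults
are the screen's conditions: the 29-residue short-ORF reference with its
wild-type codon sequence, the seven-region tiling, seven loss-of-function
singles and eight frequent compensatory pairs, tolerated singles covering
every SNS-reachable substitution, 500 reads per variant and a 0.5%
per-base error. Phenotypes follow the planted rule — a read is
mutant-phenotype iff its true genotype contains a planted deleterious
single not accompanied by its planted compensating partner — and errors
are applied to nucleotides *after* phenotype assignment, which is the
mechanism that produces ISPAs in a real experiment. Two depth choices
mirror the structure of real pools: deleterious variants grow into
colonies and dominate their pool, so they are sequenced 10× deeper than
tolerated variants; compensatory genotypes are rare events, planted at
250 reads so that their observed exact-genotype counts (after the ~35% of
reads that carry at least one error are diverted to satellite genotypes)
land in the low hundreds, the range in which published compensatory
tables report them. The generator does not emulate chimeric reads,
PCR-bias between variants, indels or quality-score structure; reads are
assumed trimmed upstream.

**Alignments** (`msa_truth()` / `simulate_msa()`). Rows are i.i.d.:
background columns substitute independently at a per-column rate (default
5%) to a uniform non-reference residue, and planted pairs co-substitute —
both or neither — at their stated rate, with background suppressed at
planted columns so the signal is clean. Defaults use 148 rows, a
realistic family size for a small toxin family. The generator does not
emulate phylogenetic correlation between rows, indel patterns beyond an
optional uniform gap rate, or amino-acid exchange preferences. Passing
recovery tests on these alignments therefore shows that the index detects
co-substitution against independent noise, not that it separates
covariation from shared ancestry in real families.

**Structures**. `make_ideal_helix()` places N, CA, C, O and CB on a
cylinder (rise 1.5 Å, twist 100°/residue, CA radius 2.286 Å) at per-atom
radii and phase offsets derived once from an ideal $\varphi = -57°$,
$\psi = -47°$ build; consecutive CA atoms come out 3.81 Å apart and the
5 Å contact map contains exactly the (i, i±1), (i, i±2), (i, i±3),
(i, i±4) backbone pattern, with i, i±4 arising from the O(i)–N(i+4)
hydrogen-bond geometry and i, i±5 just outside the cutoff (5.008 Å).
A Cα-plus-side-chain reduction alone cannot reproduce that pattern (its
closest i, i+4 atoms are ≈ 5.6 Å apart), which is why the backbone atoms
are included. `make_globular_decoy()` produces a compact self-avoiding
chain: a confined random walk with 3.8 Å steps (so the 5 Å graph is
connected through the backbone by construction), a 3.5 Å minimum
separation, and a spherical confinement allotting 113 Å³ per residue —
the packing density of folded proteins. Decoys have protein-like density
and connectivity but no secondary structure, hydrophobic core or
side-chain geometry beyond a randomly oriented pseudo-CB.

## Numerical choices

* Strict inequalities where the conventions state them: contact distance
  `< cutoff`, critical ratio `> 1`, compensatory reporting count
  `> min_count`; inclusive where they state those: ISPA `|F| ≤ e`,
  length difference `≤ 20`, identical orientation `≤ tolerance`.
* `F` is undefined at $WT_i + MUT_i = 0$ and raises an error rather than
  returning a sentinel; variants seen in one pool only get $F = \pm 100$
  and classify normally.
* Angle computation clamps cosines into $[-1, 1]$ before `acos`;
  pairwise distances clamp tiny negative squared norms (floating-point
  cancellation) to zero.
* All generators and the annealer take explicit integer seeds and restore
  the caller's RNG state; identical seeds give bit-identical output.
* Report rounding is half away from zero (base `round()` would round half
  to even); machine-precision values stay in the tables.
* Degenerate inputs error early with informative messages: empty chains,
  empty vector sets, all-equal sizes in the packing fit, overlapping
  regions, invalid annealing schedules.

## Problem sizes used by the test suite

The suites exercise the pipeline at sizes chosen to make every oracle
exhaustive and the full run complete in about a minute: clique profiles
are checked against a brute-force enumeration of all subsets of size ≤ 5
on 50 seeded 30-node random graphs; the annealed minimum distance against
1°-grid oracles on 20 seeded instances; contact maps against an all-pairs
distance scan and 100 random rigid motions; screen recovery on the full
default truth (≈ 140 000 reads); alignment recovery on 200-row
alignments with a planted pair at rate 0.3. These sizes are the package's
own testing choices; every routine accepts larger inputs.

## Known limitations

* Variant calling assumes in-frame, full-length amplicon reads; indels
  and frame-breaking reads are discarded and logged, not called.
* The correlated-mutation index treats alignment rows as independent;
  phylogenetic novelty weighting is out of scope.
* The minimum-Hausdorff search family is one-dimensional by design;
  richer alignments of contact geometries (e.g. per-vector re-matching
  with a cost model) would require a different distance than Hausdorff.
* The identical-orientation fraction depends on the chosen tolerance;
  cross-study comparisons should fix it explicitly and report the full
  distance distributions, as `compare_cohort()` does.
* CATH class labels and family alignments are inputs, not products: the
  package neither classifies structures nor builds alignments.
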