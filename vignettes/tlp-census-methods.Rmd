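---
title: "Methods: motif-delimited TLP censuses, distance phylogenies and locus statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-delimited TLP censuses, distance phylogenies and locus statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlpcensus)
```

`tlpcensus` implements a genome-wide census workflow for the thaumatin-like
protein (TLP, PR-5) family: domain delimitation and completeness filtering,
architecture classification, conservation scoring of the acidic-cleft REDDD
residues, physicochemical descriptors, a Poisson-corrected Neighbour-Joining
phylogeny with bootstrap, and tandem-cluster / transposable-element statistics
at family loci. This vignette explains the models and the numerical and design
choices behind each stage, what the synthetic-data generators emulate, and what
the test suite does and does not establish about real data.

## Domain delimitation

The thaumatin domain is delimited by two conserved boundary motifs:
`N-x-C-x(3)-V/I-W` at the N-terminal end and `Y-x-I/V-x-F-C-x` at the
C-terminal end. We read the `x(3)` notation at face value — exactly three
wildcard positions — which makes the N-terminal window 8 residues and the
C-terminal window 7. A wildcard matches any of the 20 standard residues but
*not* the ambiguity letter `X`: an unknown residue cannot certify a boundary.

When several motif occurrences exist, `extract_domain()` keeps the (N-hit,
C-hit) pair producing the longest domain whose length falls within the
configured bounds, with ties broken by smallest start. This favours full-length
domains deterministically. If no pair satisfies the bounds, the longest
compatible pair is retained so the completeness filter can report *why* it
fails rather than silently dropping the protein.

A domain is **complete** when both motifs are present, its length lies in
`[domain_min_len, domain_max_len]` (default 120–330 aa) and it contains at
least `domain_min_cys` (default 8) cysteines. The family itself does not
prescribe these thresholds; the defaults were chosen once to admit small-TLP
domains (~150 aa, 10 Cys) and the long ascomycete domains (~280 aa) while
rejecting fragments, and all three are exposed in `census_config()`. Signal
peptides are not trimmed, so the reported `coverage` (domain length over
protein length) refers to the full precursor; against mature sequences the
thaumatin domain typically covers ~95% of the protein.

## Architecture classification

`classify_tlps()` applies a decision tree:

1. no complete domain → `incomplete`;
2. a kinase region downstream of the domain → `tlp_kinase`, or
   `small_tlp_kinase` when the domain also meets the small criteria;
3. domain shorter than `small_cutoff` (180 aa) with 9–11 cysteines → `small`;
4. 14–16 cysteines → `typical`;
5. otherwise `typical` with an `atypical_cys` evidence flag.

The cysteine bands `[14,16]` and `[9,11]` encode the known 1–2-residue
exceptions in divergent fungal and animal sequences rather than demanding
strict 16/10 counts. The 180-aa cutoff splits the family's ~150 versus ~215 aa
length bimodality at a gap midpoint; it is configuration-exposed.

Kinase regions are recognized by a self-contained motif triad — glycine-rich
loop `G-x-G-x-x-G`, catalytic `H-x-D`, activation-segment `D-x-G` — required to
occur in order with start-to-start spacings of 60–140 and 15–45 residues and to
leave at least 200 residues to the protein's end. The two catalytic aspartates
(the D of `H-x-D` and of `D-x-G`) are reported in per-protein coordinates. This
is a deliberate trade against a profile HMM: it needs no external model files,
but divergent kinase domains that violate the spacing windows would be missed;
the classifier would then fall back to `typical`/`small`, which is the
conservative direction for a census.

Transmembrane segments use the classic Kyte–Doolittle heuristic: the
maximal-scoring 19-residue window of mean hydropathy, called when that mean
reaches 1.6. When domain and kinase coordinates are known the search is
restricted to the inter-domain region, where the fusion proteins carry their
predicted TM stretch.

## REDDD conservation and column conservation

The acidic cleft of typical TLPs is lined by five dispersed residues —
Arg, Glu, Asp, Asp, Asp. `reddd_score()` takes five ungapped positions on a
reference sequence (0-based, like every protein coordinate in the package),
maps them to alignment columns through the reference row's gap structure, and
scores every row per position as `identical` (canonical letter), `equivalent`
(charge-preserving swap) or `divergent` (anything else, including a gap).
Equivalence is limited to `{R,K}` at the arginine position and `{D,E}` at the
four acidic positions: "similar biochemical properties" is an open-ended
notion, and charge preservation is the defensible core of it for a cleft whose
function rests on its negative surface.

`column_conservation()` bins each column by its count *k* of distinct non-gap
residues into four levels (1: *k*=1, 2: *k*≤3, 3: *k*≤6, 4: *k*≥7), a coarse
sequence-level analogue of the four-colour conservation rendering used in
structure-mapped alignments. All-gap columns give `NA`.

## Physicochemical descriptors

Molecular weight is the sum of *average* residue masses plus one water
(18.0153 Da) — average rather than monoisotopic, matching kDa-scale family
descriptions. `X` has no defined mass and is an error (reported as `NA` by the
tidy wrapper).

The isoelectric point solves `net_charge(sequence, pH) = 0` by bisection on
pH ∈ [0, 14] to 1e-8 pH resolution. The charge model is the
Henderson–Hasselbalch sum over the termini and the ionizable side chains
(acidic D, E, C, Y; basic H, K, R) under the EMBOSS pKa set (N-term 8.6,
C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). Net charge is
strictly decreasing in pH, so the root is unique; the two-group case `GG`
returns the analytic value (8.6 + 3.6)/2 = 6.10. The pKa table is an argument,
not a constant: published pI values computed with other tools/pKa sets can
differ by a few tenths of a pH unit, so cross-tool comparisons should be read
as soft checks.

## Distance phylogeny

The phylogeny stage is implemented from first principles, exactly as a
distance workflow on protein alignments is classically specified:

- **p-distance with pairwise deletion** (`pdistance_matrix()`): per pair,
  columns where either row carries `-` or `X` are excluded; `p` is the
  fraction of differing residues over the usable columns, and the usable count
  is recorded. `X` is treated as missing alongside gaps because an unknown
  residue cannot be scored. Pairs with zero usable columns or `p ≥ 1` are
  flagged undefined; they reject tree building with an error naming the pairs.
- **Poisson correction** (`poisson_correct()`): `d = −ln(1 − p)`, the
  multiple-hit correction under rate-homogeneous substitution.
- **Neighbour-Joining** (`nj_tree()`): Saitou–Nei agglomeration with the
  standard Q-criterion and two-point branch formulas. Two numerical policies
  make it deterministic: Q-ties are broken on the lexicographically smallest
  pair of subtree labels (a merged node carries its smallest leaf label), and
  negative branch estimates are clamped to zero with the deficit transferred
  to the sibling branch so path lengths are preserved. `trace = TRUE` records
  every Q-selection for inspection.
- **Bootstrap** (`bootstrap_support()`): seeded column resampling with
  replacement; each replicate runs the full distance→NJ path; the support of
  an internal edge is the fraction of replicates containing its bipartition.
  Replicates with undefined distances cannot support any split — they count
  against every split and are tallied in a diagnostics attribute rather than
  silently discarded. Supports live in [0, 1] on the tree and are written as
  integer percentages (rounded half-up) in Newick output.

Clade assignment (`assign_clades()`) expands named anchor sets: a clade is its
anchors plus every leaf attached to an internal node of the anchors' minimal
spanning subtree. Reading the expansion literally as "leaves of the spanning
subtree" would make singleton anchors the only members and make anchors that
span the basal path claim nothing extra, which contradicts how reference
leaves are used to name clades; the attached-leaf rule reproduces all the
intended behaviours (singletons stay singletons, a cherry's two anchors claim
the cherry, anchors spanning the backbone absorb everything hanging off it).
Contested leaves and leaves outside every expansion are `unplaced`.

## Locus statistics

Genomic intervals are 0-based half-open throughout; GFF3's 1-based closed
convention is converted at the reader boundary, so GFF → internal → GFF is the
identity. Cluster and coverage arithmetic is strand-agnostic — the analysis
concerns loci, not transcripts.

`find_clusters()` marks maximal runs of family genes in which each next family
gene starts within `cluster_gap_bp` (default 100 kb) of the previous one's
end, keeps runs of at least `cluster_min_size` (default 3), and measures the
span from first gene start to last gene end. The gap default was chosen once
from the density of a known 11-gene/350-kb tandem array (mean inter-gene gap
≈ 32 kb) with headroom, and is configuration-exposed. A cluster is *exclusive*
when no non-family gene overlaps its span.

`te_coverage()` clips repeat intervals to a region and unions them within each
TE class before measuring, so overlapping annotations are never double-counted;
the total is the union over all classes. Enrichment against genome background
is a plain ratio of fractions — the analysis is descriptive, and background
fractions (e.g. 42% total TE, 5% Gypsy genome-wide in poplar) are user-supplied
numbers from genome papers, not recomputed.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground truth
recorded, so all stages are testable end-to-end without downloads.

**Protein scaffolds** (`generate_protein()`) plant the boundary motifs, a
fixed canonical template of internal cysteines (evenly spaced, stable across
seeds), the REDDD letters at fixed fractional offsets, and — for fusions — a
19-residue hydrophobic TM stretch flanked by polar linkers and a kinase region
with the anchor triad at spacings 100/30. Filler residues are drawn uniformly
from the 14 standard letters that are not motif anchors (`C,G,H,N,W,Y`
excluded), which guarantees the planted motifs are the only matches and makes
recorded coordinates exact for every seed. Typical-domain fusions come out at
exactly 650 aa.

**Alignments** (`evolve_alignment()`) evolve a root sequence along a tree: per
branch of length *b* each site substitutes with probability 1 − e^(−b), the
new residue drawn uniformly from the other 19. Along a single branch a site
never reverts, so two leaves separated by one branch of length *d* differ with
probability exactly 1 − e^(−d) and the Poisson correction is the exact
inverse. Across multi-branch paths, back-substitution enters through the 19/20
factor: `expected_pdiff()` documents the closed form and
`estimate_path_distance()` inverts it. The distance-recovery checks state
their expectation through these functions rather than pretending the Poisson
estimator is unbiased on multi-branch paths. Cysteine/REDDD freezing is used
for classifier fixtures and switched off for phylogeny fixtures so distances
are unbiased.

**Loci** (`generate_locus()`) lay out a tandem array spanning exactly the
planned width (default: 11 two-exon genes over 350 kb), optional interleaved
or distant genes, and disjoint TE intervals placed in alternating slots so the
per-class coverage of the span equals the plan exactly (defaults 37% Gypsy +
15% DNA transposon = 52% total).

What passing on this synthetic data does **not** show: the generators have no
indel process, no empirical substitution matrix, no alignment error (the
pipeline consumes alignments; it never builds them), no nested/fragmented TE
annotations, and scaffold filler has uniform composition. Results on real
data inherit the quality of the supplied alignment and repeat annotation, and
manually re-adjusted alignments are not reproducible from sequences alone —
which is why the package's validation rests on synthetic recovery rather than
leaf-by-leaf agreement with any published tree.

## Problem sizes and determinism

The shipped test-suite checks run at sizes chosen to make the statistics
decisive while keeping the suite quick: 200 seeded proteins per architecture
for classification round-trips; 1,000 random sequences against the brute-force
motif matcher; 500 random 4–8-leaf additive matrices (recovered at RF 0,
branch error < 1e-9) and 200 perturbed 5-leaf matrices against exhaustive
least-squares search; 10,000-column alignments for distance recovery at
d ∈ {0.1, 0.5, 1.0} (|d̂ − d| < 0.05); 2,000-column six-taxon simulations with
long internal branches for bootstrap calibration (200 replicates in tests,
1,000 in the acceptance script); 500 random sequences against a 1e-5 pH grid
oracle; 1,000 random interval fixtures against per-base counting.

Every stochastic component is seeded (`withr::with_seed`), and re-running a
census with identical inputs, config and seed reproduces the report
byte-identically. Open degenerate cases are handled as values, not crashes:
absence of a domain is a value, saturated distance pairs are flagged and named,
all-gap columns are `NA`, an empty repeat table gives coverage 0.

## Known limitations

- Motif matching is exact; a single substitution in a boundary motif of a
  divergent sequence makes the domain incomplete. A mismatch-tolerant mode
  would need a scoring model the family description does not provide.
- Kinase detection is a heuristic triad, not PF00069; see above.
- No allele deduplication: when two assembly versions predict allelic copies,
  the census counts what it is given.
- pI values depend on the pKa set; only same-table comparisons are exact.
- NJ is O(n³) in pure R; fine for family-scale trees (tens to a few hundred
  leaves), not for thousands of taxa.
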