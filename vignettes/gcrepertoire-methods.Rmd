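---
title: "Methods: clonal analysis of individual germinal-center repertoires"
author: "gcrepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal analysis of individual germinal-center repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `gcrepertoire`, the conventions
and numerical choices that are not forced by the science, and what the
synthetic-data generator does and does not emulate.

## Data model

A rearrangement table holds one row per sequenced V(D)J rearrangement.
Since the data model targets genomic DNA, one rearrangement is one B
cell: `duplicate_count` is a cell count, and non-functional
rearrangements are first-class observations. Coordinates held in memory
are 0-based, half-open on the ungapped sequence; the on-disk AIRR
Rearrangement TSV dialect (1-based, inclusive) is converted only at the
I/O boundary, so `read_rearrangements(write_rearrangements(x))` is the
identity. Records that violate the structural invariants (junction
length, region ordering, N-regions inside the junction span) are dropped
with a warning and kept in a `rejected` attribute — a QC-filter mindset
rather than a hard failure, because a large Rep-seq table with a handful
of malformed rows should not abort an analysis.

## Clone definition

Two sequences belong to the same clone when they share the V gene
(allele stripped), the J gene, the junction length, and more than 84%
junction nucleotide identity. Identity between equal-length junctions is
position-wise (Hamming), because length equality is a hard key; edits
are substitutions by construction. Within each (V, J, length) partition
the junctions are clustered by hierarchical agglomerative clustering and
cut at distance `1 - threshold` (exclusive, so identity exactly at the
threshold does not merge). The linkage criterion is **single linkage**
by default: clonal lineages diversify by chaining, and single linkage is
the standard choice for junction clustering; `complete` and `average`
are available for sensitivity analyses. Ties when choosing a clone's
representative (equal duplicate counts) are broken lexicographically by
sequence id, and position-wise consensus ties by alphabetical base —
neither choice is scientifically forced, both make results
order-independent.

`optimize_threshold()` re-derives the threshold from the data: the
distance of each record to its nearest same-(V, J, length) neighbour
within the sample, and against a negation set (sequences known to be
clonally unrelated, e.g. a different individual). Distances here are
normalized Levenshtein, the package's string metric. The two
distributions combine into a bimodal shape — a low within-clone mode and
a high unrelated mode — and the chosen threshold is `1 - d*`, where `d*`
minimizes the pooled Gaussian kernel density (Silverman's bandwidth)
between the two modes. When the modes do not separate (e.g. a sample of
pure singletons) no threshold is returned, with a warning. Note that the
location of a kernel-density valley depends on the relative mass of the
two modes: in realistic samples where within-clone pairs dominate the
low mode, the valley sits near the low mode and thresholds land around
0.8–0.9.

Because the assay misses the first 15–20 FWR1 residues, V-gene calls
within a subgroup are not fully reliable; `merge_same_subgroup()` merges
clones with equal (subgroup, J, junction length) and identical
representative junction, keeping the larger partner's identity.

## Diversity

All indices are duplicate-count weighted (cells, not unique sequences);
an unweighted analysis can be run by resetting `duplicate_count`.
Entropy is in natural log units and `^1D = exp(H)`. The coverage-adjusted
entropy is the Chao–Shen estimator: coverage `C = 1 - f1/n`, adjusted
abundances `p~ = C p`, and a Horvitz–Thompson-style denominator
`1 - (1 - p~)^n` per term. When every clone is a singleton the coverage
is zero and the estimator is undefined; the plug-in entropy is returned
with a warning. Evenness `exp(H)/N_Chao` is clipped to [0, 1] because
the two estimators are computed independently and can transiently
violate the bound. The dominant clone is unique by construction (ties
broken by clone id); "expanded" means frequency strictly above 1%.

## Functionality classes

Frame status is evaluated before stop-codon scanning, so a frameshifted
junction is `out_of_frame` regardless of stops — consistent with
frameshifts being the dominant source of non-functional rearrangements.
For in-frame sequences, a stop codon whose codon span overlaps any
N-region interval by at least one nucleotide is attributed to V(D)J
recombination (`vdj_stop`), otherwise to SHM (`shm_stop`); partial
overlap counts because the attribution rule does not define it and a
single inserted nucleotide inside a codon already makes the codon
recombination-derived. An in-frame stop-bearing record without N-region
bounds is an error: the two causes cannot be distinguished.

Allele pairing assumes a B cell carrying a non-functional passenger
allele contributes equally many cells to both rearrangements. Matching
is greedy within each GC, processing NF clones by descending abundance
and accepting the closest functional clone in `|log2(NF/F)|` up to 1
(i.e. at most a twofold difference), both clones gated on presence in
both replicates. The tolerance and the greedy order are conventions
chosen for determinism; they are recorded in the output. With hundreds
of clones at similar abundance the *identity* of the matched partner is
not identifiable from abundance alone — the pairing is a population-level
summary, not a per-clone assignment, and the tests treat it that way.

The mutational spectrum uses each clone's position-wise majority
(duplicate-weighted) as reference, so it measures within-clone
diversification rather than distance to germline; singleton clones
contribute nothing. R/S classification compares codons against the
germline V segment; the junction has no germline, so clone consensus
would be the reference there and the default summary restricts to the V
segment. R/S ratios report `Inf` when S = 0 with R > 0 and `NaN` for
0/0, with counts attached, rather than inventing a finite value.

## Recirculation model

A clone "belongs" to a GC only when found in both PCR/NGS replicates of
that GC. The occupancy k (number of gated GCs) is modeled as
`k = 1 + N`, `N ~ Poisson(mu)`: every observed clone occupies its
founding GC and seeds N others. Under this convention the MLE is the
closed form `mu = mean(k) - 1`, and `P(N >= 1) = 1 - exp(-mu)` matches
the reactivation-probability arithmetic. Whether the home GC should
count as an occurrence is a modeling choice, so a zero-truncated
parameterization (observed `k >= 1` from a Poisson,
`mu/(1 - exp(-mu)) = mean(k)` solved by `uniroot` on [1e-8, 100]) is
also provided, and every fit is labeled with its convention.
All-`k = 1` histograms return `mu = 0` with a degeneracy flag.

## Lineage trees

Unique (sequence, GC) pairs are collapsed into weighted leaves, at most
`max_leaves = 300` kept by weight. The root is germline V + consensus
junction + germline J. Distances are normalized Levenshtein
`2 Lev/(|a|+|b|+Lev)` — symmetric, in [0, 1], and triangle-inequality
compliant — and trees are built by neighbor joining (via `ape`), then
rooted at the root tip. With one or two taxa besides the root the tree
is constructed directly (cherry, or the exact three-point solution).
Mutations-before-crippling takes, per maximal non-functional subtree,
the member closest to the root and counts its differences to the root
excluding the crippling stop codon itself — the subtree-minimum
convention avoids counting post-crippling drift.

## Convergence metrics

CDR similarity, paratope identity ("Paratype") and the structural token
score ("Ab-Ligity"-style) vote independently at thresholds 0.84, 0.76
and 0.26; a pair is predicted to share an epitope with at least two
positive votes *and* equal CDR3 length. The token score enumerates all
residue triples of a paratope, each tokenized by its sorted
chemical-class triple (aliphatic A/V/L/I/P/G/M, hydroxyl S/T, sulphur C,
aromatic F/W/Y/H, acidic D/E, amine N/Q, basic K/R) and its sorted
pairwise distances binned at 1 Å, and compares token multisets by
Tanimoto; bin width and thresholds are arguments. A metric abstains —
casts no vote — when its inputs are missing (empty paratope, no
coordinates, fewer than three paratope residues); an abstention cannot
substitute for a positive vote, which is the conservative reading.
Paratopes are aligned by residue numbering on a fixed frame (V segment,
then CDR3 by offset), not by global alignment, matching the
germline-filled FWR1 convention. In the all-pairs screen the token score
is evaluated lazily, only for equal-CDR3-length pairs where the first
two metrics leave the vote undecided or already predicted; elsewhere it
is reported as `NA` and can change no decision.

Epitope groups are connected components of predicted pairs among each
GC's top-`rank_threshold` clones. The raw epitope-count estimate is the
number of components; since missed pairs fragment components, a
recall-corrected count scales the raw count by an assumed pair recall
(default 0.1).

## The synthetic lymph node

`generate_lymph_node()` emulates the experimental design: 10 GCs, two
replicates each, heavy-tailed clone sizes, 90% functional sequences with
non-functional composition 0.78/0.11/0.11
(out-of-frame / V(D)J stop / SHM stop), inter-GC sharing at Poisson mean
0.25, SHM with threefold-elevated CDR rates, a mean of 3.6 mutations
before an SHM crippling stop, skewed V-gene usage, and planted
common-epitope clone groups. Choices the data model does not dictate:

- **Clone sizes** follow a stick-breaking (GEM) process. No generative
  law is reported for clone sizes, only a per-GC dominance range of
  roughly 5–30%; a per-GC concentration drawn uniformly from
  `[alpha/2, 2 alpha]` with `alpha = 12` reproduces that spread while
  modeling GCs as distinct competitive environments.
- **Sharing** is "home GC + Poisson(mu) extra GCs", with abundance in
  non-home GCs down-scaled ×0.1 (a re-seeding B cell competes at a
  disadvantage). The latent Poisson draw is recorded as ground truth, so
  the fit convention can be checked against it directly.
- **Class masses are balanced per GC**: the per-class clone weights are
  rescaled so the *expected* functional fraction and non-functional
  composition equal their targets exactly, leaving only multinomial
  noise. Without this, the heavy-tailed clone sizes make class fractions
  fluctuate by several percentage points between seeds.
- **Crippled sublineages**: a fraction of functional clones carries a
  crippling stop planted after `Poisson(3.6)` prior mutations; crippled
  cells acquire few further mutations (mean 0.5), modeling their short
  remaining lifespan, which keeps the subtree-minimum estimator nearly
  unbiased.
- **Epitope groups** are planted among the largest functional clones:
  members share a V gene, J gene, junction length and a conserved
  junction scaffold, and differ in a hypervariable window (a third of
  the junction, resampled per member with at least 12 nt separation) —
  so they are unambiguously distinct clones with convergent CDR flanks.
  Convergent selection is modeled by suppressing SHM on CDR1/2, the
  conserved junction codons and the planted paratope residues of these
  clones. Paratope probabilities and toy coordinates derive from a
  per-group template perturbed by `paratope_noise`.
- **Replicates** are independent multinomial draws from the same GC
  pool, so rare clones drop out of single replicates and the
  consistency gate has work to do. Unique SHM variants per sample are
  drawn at ~0.4 per cell, which produces the singleton/doubleton
  structure the Chao estimators need.
- The bundled germline set is synthetic: 12 V segments (240 nt, fixed
  region layout), 4 J segments (36 nt) and 6 D segments named after
  common human genes. Fixed segment lengths keep residue numbering
  trivially alignable across clones; this is a simplification real IMGT
  numbering handles with gaps.

What the generator does **not** emulate: PCR/sequencing error beyond
substitutions, indels and alignment artifacts, AID hotspot motifs,
affinity-dependent selection dynamics, realistic germline allele
diversity, or light chains. Tests passing on this generator therefore
validate the estimators and the pipeline logic — threshold behavior,
estimator bias, gate semantics, recovery of planted structure — not
robustness to annotation noise in real data.

## Problem sizes and runtime choices

The test suite and the acceptance script run the pipeline at desk scale:
20,000 cells (10 GCs × 2 replicates × 1,000) for class-fraction and
pipeline-recovery checks, 5,000 clones × 200 replicates for the
Poisson-recovery bias bound, 1,000 random string pairs for the
Levenshtein oracle, and 5-leaf trees for the exhaustive topology oracle.
The generator default of 5,000 sequences per sample (the study scale is
~100,000) is used when a larger simulation is wanted explicitly.

## Known limitations

- Exact-partner identification in allele pairing is not possible from
  abundance alone at realistic clone counts (see above).
- The KDE-valley threshold depends on the mass balance of the two
  distance modes; for samples dominated by large clones the valley
  drifts toward the midpoint of the modes.
- The epitope-count estimate inherits whatever pair recall is assumed;
  it is reported together with that assumption rather than as a single
  number.
- Trees are distance-based (NJ); no likelihood model of SHM is used, so
  branch lengths are normalized edit distances, not mutation-time
  estimates.
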