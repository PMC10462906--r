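# gcrepertoire

Clonal analysis of B-cell receptor (BCR) heavy-chain repertoires sequenced
from **individual germinal centers** (GCs) of a lymph node.

Laser capture microdissection makes it possible to sequence the IGH
repertoire of single GCs from genomic DNA, with two PCR/NGS replicates per
GC. Because one V(D)J rearrangement equals one B cell, duplicate counts are
cell counts and non-functional rearrangements (frameshifted alleles, stop
codons from V(D)J recombination or somatic hypermutation) are observed
alongside functional ones. This package implements the per-GC analysis of
such data for immunologists and computational biologists: clone definition
and diversity, functionality classes and allele pairing, inter-GC clone
sharing under a Poisson reactivation model, per-clone lineage trees, and
prediction of clone pairs with common epitope reactivity. A synthetic
multi-GC generator with full ground truth makes every stage testable.

## Models and statistics

**Clones.** Sequences belong to one clone when they share the V gene, J
gene and CDR3 (junction) length, and exceed 84% junction nucleotide
identity under single-linkage agglomerative clustering
(`group_clones()`). The threshold can be re-derived from the
distance-to-nearest distributions of the sample and a negation set
(`optimize_threshold()`). Clones with different V genes from the same
subgroup are merged when the junction of their most common sequence is
identical (`merge_same_subgroup()`).

**Diversity** (`diversity_profile()`), in Hill's ^qD notation:

- dominance: max_i p_i (relates to 1/^∞D);
- richness ^0D, bias-corrected Chao1: N_obs + f1(f1−1) / (2(f2+1));
- Shannon entropy log ^1D, coverage-adjusted (Chao–Shen): with coverage
  C = 1 − f1/n and p̃_i = C·p_i,
  H = −Σ p̃_i ln p̃_i / (1 − (1 − p̃_i)^n);
- evenness: exp(H)/N_Chao ∈ [0, 1].

Sample similarity is the Sørensen–Dice coefficient
1 − Σ_i |x_i − y_i| / 2 on normalized clone abundances
(`dice_similarity()`).

**Functionality.** Each sequence is functional, out-of-frame, or carries a
stop codon attributed to V(D)J recombination (stop inside an N-region) or
to SHM (stop elsewhere); clones with 5–95% productive sequences are mixed
F&NF clones (`classify_sequences()`, `classify_clone()`). Non-functional
passenger alleles are paired to functional alleles of similar abundance
(`pair_alleles()`).

**Recirculation.** A clone consistently present (both replicates) in
k GCs occupies its home GC plus N extra ones; N is modeled as Poisson with
mean μ = λt, so μ̂ = mean(k) − 1 in closed form, the reactivation
probability is P(N≥1) = 1 − e^(−μ), and the per-day seeding rate is μ/t
for a GC lifetime t (`sharing_histogram()`, `fit_poisson()`).

**Lineage trees.** Per-clone neighbor-joining trees on normalized
Levenshtein distances, Lev_norm = 2·Lev/(|s1|+|s2|+Lev), rooted at
germline V + consensus junction + germline J (`clone_tree()`); the timing
of crippling SHM stops is read off the tree
(`mutations_before_crippling()`).

**Convergence.** Clone pairs are predicted to bind a common epitope when
at least two of three metrics pass and CDR3 lengths are equal
(`predict_common_epitope()`): CDR similarity (mean normalized Levenshtein
over H1–H3, threshold 0.84), paratope identity (matching predicted
paratope residues over the smaller paratope, threshold 0.76), and a
structural token score over residue triples (chemical class + binned
pairwise distances, Tanimoto, threshold 0.26). Connected components of
predicted pairs among dominant clones form epitope groups
(`epitope_groups()`, `estimate_epitopes()`).

## Worked example

```r
library(gcrepertoire)

cfg <- lymph_node_config(seqs_per_sample = 500, clones_per_gc = 120, seed = 7)
ln  <- generate_lymph_node(cfg)

clones <- group_clones(ln$records, threshold = 0.84)
clones
#> clone_set: 733 clones from 4056 records (threshold 0.84 , linkage single )

ab  <- clone_sample_abundance(clones, ln$records)
gc1 <- ab[ab$gc_id == "GC01", ]
x   <- clonal_abundance(tapply(gc1$abundance, gc1$clone_id, sum), "GC01")
diversity_profile(x)
#>   sample_id    n dominance richness_obs richness_chao shannon_chao evenness f1 f2 coverage
#> 1      GC01 1000     0.079          102           127         3.89    0.384 29 15    0.971

table(classify_sequences(ln$records)$functional_class)
#>   functional out_of_frame     shm_stop     vdj_stop
#>         3642          311           62           41

fit <- fit_poisson(sharing_histogram(clones, ln$records), lifetime_days = 20)
fit
#> Poisson reactivation fit (shifted): mu = 0.0640, P(N>=1) = 6.2%
#>   seeding rate: 0.003198 per clone per day (lifetime 20 d)
```

GC01 holds 102 observed clones (Chao1 estimate 127, i.e. ~25 clones were
missed at this depth), its dominant clone holds 7.9% of cells, and ~90% of
sequences are functional with frameshifts dominating the non-functional
part. The fitted μ is smaller than the latent seeding rate because shared
clones enter foreign GCs at low abundance and the replicate-consistency
gate is conservative at shallow sampling depth.

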