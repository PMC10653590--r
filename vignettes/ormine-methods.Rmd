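---
title: "Mining and comparative analysis of olfactory receptor subgenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparative analysis of olfactory receptor subgenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Olfactory receptor (OR) genes are the largest multigene family in mammal
genomes: hundreds to thousands of short (< 1 kb), intronless
G-protein-coupled receptor genes, plus a comparable number of
pseudogenes. Because the genes are single-exon and family structure is
well conserved (13 monophyletic families: class I = 51, 52, 55, 56;
class II = 1-3-7, 2-13, 4, 5-8-9, 6, 10, 11, 12, 14), the whole
repertoire of a species can be mined directly from its genome assembly
by profile homology search, and the per-species counts can then be
analysed as continuous traits on a dated species tree.

`ormine` implements that whole chain: profile construction and
translated genome scanning, redundancy merging, a phylogenetic filter
against non-OR GPCRs, functional classification
(functional / sub-7TM / pseudogene), per-species repertoire tables, and
the comparative statistics used downstream (Pagel's lambda,
BM/OU model selection, phylogenetic Tukey contrasts, multivariate
phylogenetic model comparison with MANOVA, PCA of family proportions,
and ML ancestral states). A synthetic-data module generates
ground-truthed genomes and traits so that every stage is testable
against known truth.

# The mining pipeline

## Profiles and translated scan

Each OR family is modelled as a position-specific scoring matrix
(log-odds PSSM) over amino acids, built from a center-star alignment of
the translated seed coding sequences with background-proportional
pseudocounts against a uniform residue background. Because OR genes are
intronless, an amino-acid profile scanned against the six-frame
translation of the assembly is equivalent to a nucleotide-level scan,
and makes frameshift evidence directly visible (a frameshifted gene
simply switches frame midway).

The scan splits every profile into contiguous chunks of roughly 52
columns and scores each chunk at every placement in every frame in one
pass over the profile columns. A chunk is significant when its log-odds
score reaches `log(db_size / evalue)` nats, where `db_size` counts all
amino-acid positions scanned (six frames) and `evalue` defaults to
1e-10; with no published threshold to follow, this default is
deliberately conservative and is recorded in the hit metadata. Each
significant chunk votes for a locus; votes on the same contig and
strand within 200 nt are chained, so stop-disrupted, frameshifted and
truncated genes are still anchored by their intact chunks while a
truncated gene's locus stays confined to the matched region. A match
reaching the final profile column is extended by one codon so the
terminal stop codon travels with the gene. Overlapping loci keep the
best-scoring family. Coordinates are 0-based half-open (BED
convention) with strand-corrected sequence extraction.

## Redundancy merge

Assemblies carry alleles and duplicated haplotype blocks; candidate
loci are therefore collapsed by greedy incremental clustering at 98%
global nucleotide identity (matches divided by full alignment length,
gaps counted against identity). Sequences are visited longest-first
with ties broken by (contig, start), which makes the result
deterministic; each sequence joins the first representative at or above
the threshold or founds a new cluster.

## Phylogenetic non-OR filter

Profile search alone admits close GPCR relatives (melanocortin-,
trace-amine-, serotonin-receptor-like sequences). Each deduplicated
candidate is placed on a neighbor-joining tree together with a
reference panel (26 verified OR proteins, two per family, and 11 non-OR
GPCRs); distances are amino-acid p-distances from pairwise global
alignments, so no multiple alignment is needed. The tree is rooted on
the non-OR reference farthest from the candidate — a non-OR rooting
that can never sit on the candidate's own attachment edge, which
matters because non-OR GPCR lineages are generally *not* monophyletic
relative to the OR radiation. Walking rootward from the candidate, the
first clade containing any reference decides the verdict: the candidate
is kept iff that clade contains at least one OR reference. Verdicts
propagate from representatives to their cluster members.

## Functional classification

A candidate is a pseudogene iff it has a premature stop, a frameshift,
or is shorter than 650 nt (the minimum length able to encode seven
transmembrane helices; 650 itself passes). Stop and frameshift evidence
come from one local alignment of the candidate nucleotides to the
best-matching family's reference coding sequence: indels whose length
is not divisible by 3 are frameshifts, and stops are read in the
reference-anchored frame between indels, ignoring a stop aligned to the
reference's own terminal codon. Anchoring requires both 30% identity
and 30% coverage — identity alone is not enough, because a short local
alignment of unrelated sequence can be locally near-identical.
Unanchored candidates fall back to a longest-ORF stop check.

Disruption-free, full-length candidates are then screened for the
seven-helix topology. The package ships a deterministic hydropathy
scanner (Kyte-Doolittle scale, 19-residue window, threshold 1.6, helix
segments merged across gaps shorter than 5 and required to span at
least 15 residues). This is an explicit stand-in for trained
neural topology predictors: it is exact on the planted-helix synthetic
proteins used throughout the tests, and the stage is pluggable so a
stronger predictor can be substituted for real proteomes. Sequences
passing all pseudogene checks with a helix count other than seven are
labelled `sub7TM` and are excluded from the functional set but counted
in the repertoire total.

## Repertoire tables

`summarize_repertoire()` produces per-species rows with the 13
per-family functional counts, sub-7TM, pseudogene and removed counts,
and two functional fractions: `fraction_functional`
(functional / (functional + sub7TM + pseudogene)) and
`fraction_functional_fp` (functional / (functional + pseudogene)).
Both conventions are reported because published repertoire summaries
use both, depending on whether sub-7TM sequences are counted in the
denominator. Family proportions divide each species' family counts by
its functional total; the optional column rescaling divides each family
column by its mean (so each family has mean 1), the normalization used
for heatmaps and ordination. Medians use the mid-mean convention for
even sample sizes.

# Comparative statistics

All trait functions align named trait vectors to tree tip labels after
whitespace-to-underscore normalization; mismatches are errors, never
silent drops.

**Pagel's lambda.** The off-diagonal entries of the Brownian covariance
`C` (shared path lengths on the dated tree) are scaled by
`lambda` in [0, 1]; the root state and rate are profiled analytically
and lambda is optimized by golden-section search with the endpoints
checked explicitly, so boundary MLEs are reported (and flagged), never
silently clamped. The LRT against `lambda = 0` uses a chi-square with
1 df; at a boundary MLE of 0 the statistic is 0 and P = 1.
`lambda = 1` reproduces the BM likelihood to numerical precision.

**BM and OU fits.** BM MLEs are closed-form GLS (for two tips the rate
is `(x1 - x2)^2 / (2 (t1 + t2))`). OU models use the root-conditioned
covariance
`V_ij = sigma2/(2 alpha) exp(-alpha d_ij) (1 - exp(-2 alpha t_ij))`
on an ultrametric tree, which reduces exactly to BM as `alpha -> 0`.
That nesting is essential for honest model selection: a stationary OU
form (which degenerates to an all-ones correlation at small `alpha`)
is not nested in BM and lets regime models spuriously beat BM on BM
data. Regimes are mapped at the tips; tip means are the regime optima
(the optima-reached convention). `alpha` is optimized on a log scale
with boundary flags; AIC uses k = 2 (BM) and k = 2 + #regimes (OU).

**Phylogenetic Tukey contrasts.** A cell-means GLS under `sigma2 * C`
yields all pairwise group contrasts with GLS standard errors
(variance estimated with n - g denominator). Family-wise adjustment is
single-step max-|z| by seeded Monte Carlo (default 50,000 draws taken
in the full-rank group-mean space and projected through the contrast
matrix, because pairwise contrasts are linearly dependent), with Holm
available as a deterministic fallback; the method is recorded in the
result. On a star tree the contrasts reduce exactly to ordinary OLS
Tukey-type contrasts.

**Multivariate model comparison.** Species-by-families matrices are fit
by multivariate GLS under BM and OU regime models (single `alpha`, the
among-trait covariance profiled analytically). Models are ranked by
small-sample AICc (penalty `2k(k+1)/(np - k - 1)`); plain AIC is also
reported. AICc is the default because at these problem sizes
(tens of species, 13 traits) plain AIC measurably over-selects the
regime models under a BM truth, while AICc recovers the generating
model in >= 90% of simulations in both directions. A Pillai-trace
MANOVA on the GLS-whitened data tests each regime effect, with the
large-sample chi-square approximation (df = p * q); at the package's
problem sizes this approximation is adequate for screening and is
labelled as such in the output.

**Ordination and ancestral states.** PCA is the eigendecomposition of
the centered (and by default unit-variance scaled) family-proportion
matrix; component signs are fixed by making each loading column's
largest-magnitude entry positive. Both the raw-proportion and the
column-rescaled inputs are supported, since both normalizations are in
use for this analysis. Ancestral states under BM are GLS conditional
expectations for every internal node, with variances that include
root-state uncertainty; the root estimate equals the GLS root state.

# The synthetic-data generator

The generator defines the study conditions the package is validated
under. Templates are 310-residue seven-transmembrane proteins: a
20-residue N-terminal loop, seven 22-residue hydrophobic blocks (I, L,
V, F) separated by 19-residue strongly polar loops, and a 22-residue
tail, back-translated to a 933-nt CDS. Strongly polar loops keep helix
boundaries sharp under the hydropathy stand-in even after ~10%
divergence — this deliberate coupling between the generator and the TM
scanner is what makes "intact plant implies functional" hold by
construction. Divergence operators resample any substitution that
would create an in-frame stop, so a plant's intended status is
guaranteed at any divergence. Pseudogenization operators plant a TGA
at a mid-sequence codon, insert/delete a given number of bases, or
truncate; non-OR decoys derive from three GPCR-like lineages built at
35% amino-acid divergence from class II templates — close enough for
the scan to pick up, far enough for the phylogenetic filter to remove.

The standard validation genome (`make_validation_genome()`) plants 20
genes in 120 kb of iid background: 10 intact (one per family for 10
families), 4 stop-disrupted, 3 frameshifted (indel lengths 1, 2, 4), 2
truncated below 650 nt, and 1 decoy. Families occurring twice carry a
5% base divergence so distinct paralogs stay below the 98% allele
threshold; the `divergence` argument adds a sweep on top. Background
is iid nucleotide sequence at a chosen GC content: sufficient for
specificity checks, but it contains no repeats, isochores or assembly
gaps, so passing these tests bounds algorithmic correctness, not
performance on real genomes.

Trait simulation draws exact multivariate normals from the model
covariance (BM with lambda scaling, or the root-conditioned OU above),
with explicit seeds everywhere.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline on 120-kb
single-contig genomes with 20 plants, and the comparative statistics on
64-tip balanced trees (signal and model selection; 13-trait matrices,
100 replicates per direction), a 24-tip dated tree (Tukey null, 500
replicates), and trees up to 10 tips for exact-oracle comparisons.
These sizes were chosen so every property is computed from scratch in
minutes on one core while keeping the Monte Carlo margins comfortable.

Other fixed choices: uniform amino-acid background and pseudocount mass
1 per profile column; stops score -8 and X scores 0 at every profile
column; chunk width ~52 columns; chain gap 200 nt; clustering gap
penalties (open 5, extend 2) at the nucleotide level; lambda optimizer
tolerance near machine precision with explicit endpoint comparison;
`alpha` searched in `[1e-4, 1e3] / tree depth`. Ties in family
assignment break lexicographically by family id. Degenerate inputs
(constant traits, zero-variance columns, empty families, non-ultrametric
trees for OU, p >= n trait matrices) raise informative errors rather
than propagating silently.

# Known limitations

* The hydropathy TM counter is a stand-in; on real proteomes a trained
  predictor will disagree with it on a non-trivial fraction of borderline
  sequences, which is why the sub-7TM class is kept separate rather than
  folded into pseudogenes.
* The scan models single-exon genes only; no splicing, no
  contig-boundary handling beyond the length rule.
* The per-candidate filter uses NJ on p-distances; an external
  maximum-likelihood tree builder can be substituted where higher
  resolution is needed.
* Real-data quantities that depend on external inputs (a published
  mammal timetree, curated ecological factors, published per-species
  count tables) are supported as inputs but are not reproduced by the
  test suite, which is strictly synthetic-truth based.
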