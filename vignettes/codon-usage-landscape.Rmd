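---
title: "Mapping codon usage landscapes of multipartite genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping codon usage landscapes of multipartite genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscape)
```

## The problem

Bacteria with multipartite genomes — a chromosome plus megaplasmids,
chromids and a pool of accessory plasmids (the plasmidome or mobilome) —
show systematic differences in synonymous codon usage between their
compartments. Recently acquired genes (strain-specific singletons, mobile
plasmid genes) tend to carry an AT3-leaning, translationally suboptimal
usage; anciently conserved core genes drift toward codons read efficiently
by the cell's tRNA pool, which in GC-rich soil alphaproteobacteria also
means G/C-ending codons. `codonscape` implements the statistical machinery
to map this landscape: modal codon usage estimation, resampling-based
distances between gene-set usages, tRNA-adaptation indices, ordination and
tree views, pan-genome partitioning, and plasmidome contig triage — plus a
seeded synthetic-genome generator so every stage can be exercised and
validated without external data.

## Modal codon usage

The *modal* codon usage of a gene set is the usage profile matched by the
largest number of genes — a mode, not an average. On a set contaminated by
a minority gene pool with divergent usage, the pooled (average) usage is
pulled toward the minority; the mode is not. The estimate is iterative:

1. Initialise with the pooled usage (within-family frequencies of the
   summed codon counts).
2. Score every gene against the current profile with a per-family
   chi-square match test: within each amino-acid family present in the
   gene, Pearson's \(X^2 = \sum_c (O_c - E_c)^2 / E_c\) with
   \(E_c = n_{aa} f_c\); the family statistics are summed and referred to
   \(\chi^2\) with \(\sum_{aa} (k_{aa} - 1)\) degrees of freedom.
3. Recompute the profile as the weight-pooled usage with per-gene weight
   \(w = \min(1,\; p / p_{\mathrm{match}})\), where
   \(p_{\mathrm{match}} = 0.1\) by default.
4. Iterate until the L1 change falls below `tol` (default `1e-6`).

Two design choices deserve explanation.

**Pearson rather than likelihood-ratio.** A typical 300-codon gene gives
rare amino acids (Cys at ~1% of a bacterial proteome) expected counts of
2–3. The likelihood-ratio G statistic is visibly over-dispersed there
(measured null mean ≈ 1.10 × df), so its p-values pile up near zero and
every downstream use of "does this gene match?" is biased. Pearson's
\(X^2\) has null mean exactly equal to its degrees of freedom at any
expected count; measured against 2,000 simulated matching genes its
p-values are uniform to a Kolmogorov–Smirnov statistic of ~0.02.

**Saturating rather than proportional weights.** Weighting genes by the
raw p-value is also mode-seeking, but under homogeneity the p-values of
perfectly matching genes are uniform on (0,1), and which genes happen to
score low correlates with the direction of their sampling noise. Feeding
those weights back through the iteration amplifies the estimator's error
by roughly half again over the pooled maximum-likelihood estimate
(measured 0.090 vs 0.061 mean recovery distance at 500 genes × 300
codons). The saturating weight gives every gene matching at
\(p \ge p_{\mathrm{match}}\) full weight, so on a homogeneous set ~90% of
genes carry weight 1 and the modal estimate keeps the pooled estimator's
efficiency, while genes from a divergent minority still fade smoothly to
zero. Raw-p weighting remains available (`weighting = "pvalue"`).

Other numerics: profile frequencies are floored at `1e-4` (renormalised)
before computing expectations so an observed codon never meets zero
expectation; a detected period-2 oscillation of the iteration is resolved
by averaging the last two iterates and returning `converged = FALSE`;
genes with fewer than 50 informative codons are flagged (the chi-square
approximation degrades) but not excluded.

## Distances, bootstrap and the pooled-shuffle null

The distance between two usage profiles is the Euclidean norm of the 18
per-family Manhattan distances:
\(d = \sqrt{\sum_{aa} \left( \sum_{c \in aa} |f^A_c - f^B_c| \right)^2}\).
Note the factor-two convention: a 2-codon family flipped from (1,0) to
(0,1) contributes a Manhattan distance of 2, so \(d \le \sqrt{72}\) and
the metric is twice the total-variation distance family-wise. Families
unobserved in either profile are dropped pairwise and logged.

Uncertainty comes from a bootstrap (each replicate resamples each set with
replacement to its own size and refits both modes); the null comes from
pooling the two sets and re-partitioning at random into the original
sizes. Each replicate draws its RNG substream from a counter, so
extending `n_reps` never reshuffles earlier replicates.

**Which p-value to trust.** `distance_estimate()` reports two. `p_perm`
compares the observed point distance with the shuffled-null replicate
distribution; because under the null hypothesis the observed partition is
exchangeable with the random ones, this p-value is exact (and floored at
`1/(n_reps+1)`). `p_value` compares the bootstrap and null replicate
*distributions* by a z-test (when a Shapiro–Wilk check on up to 500
replicates accepts normality) or a two-sided Mann–Whitney test. That
comparison is the right tool for asking whether two *different* distances
differ (d(A,B) vs d(C,D)), but as a null-hypothesis test of a single pair
it is structurally anti-conservative: bootstrap replicates carry
resampling variance on top of the sampling variance the null replicates
measure, so the two distributions differ in location by a factor of about
\(\sqrt 2\) even when the sets share one pool, and with hundreds of
replicates the Mann–Whitney test will detect that inflation almost surely.
`p_perm` is therefore the default significance measure for "are these two
sets' usages distinguishable"; its measured type-I error at \(\alpha =
0.05\) over 200 same-pool trials is 2–5%.

A limitation worth knowing: with an *extremely* bimodal pool (two
components separated by several distance units, mixed ~50/50), the
mode-seeking estimator can lock onto different components in the two
shuffled halves, making the null distribution itself bimodal. This does
not arise along the moderate gradients the generator emulates, but it
means the shuffle test should not be read as a general two-sample test
for arbitrary mixtures.

## tRNA adaptation (tAI and m-tAI)

Codon adaptiveness is
\(W_i = \sum_j (1 - s_{ij})\, \mathrm{tGCN}_j\) over the anticodons that
pair with codon *i*; weights are \(w_i = W_i / \max W\), with zero-\(W\)
codons imputed by the geometric mean of the nonzero weights. The default
pairing rules are the classic set — Watson–Crick pairs at \(s = 0\) plus
one standard wobble pairing per codon (G:U 0.41, I:C 0.28, I:A 0.9999,
U:G 0.68); species-specific fitted \(s_{ij}\) tables are read from TSV
and substitute for the defaults. A gene's tAI is the geometric mean of
\(w\) over its sense codons (stop codons excluded; ATG and TGG included —
their single-codon families contribute a constant factor; the choice
shifts absolute values slightly, never trends).

The modal tAI (m-tAI) scores a whole gene set by its modal usage. The
analytic mode evaluates \(\exp \sum_i f_i \ln w_i\) with
\(f_i = \mathrm{comp}(aa(i)) \cdot \mathrm{profile}(i)\); the simulated
mode generates an artificial sequence of 10,000 codons that preserves
both the modal usage and the amino-acid composition and scores it as a
gene. The analytic value is the infinite-length limit of the simulated
one; at 10,000 codons they agree within ~0.005 (10,000 codons are needed
so rare amino acids — ~100 codons each — represent their family's usage).
The analytic mode is the default; the simulated route is kept for
cross-validation and fidelity to the artificial-sequence construction.

## Ordination and trees

Correspondence analysis runs on the genes × 59 RSCU matrix (RSCU rather
than raw counts removes amino-acid composition effects and length). Genes
missing an entire amino-acid family would produce undefined RSCU entries;
they get zeros and are flagged — at typical gene lengths this touches only
rare-family-free short genes, but it is a documented divergence risk for
very short inputs. The implementation is the standard SVD of standardised
residuals; total inertia equals the table's \(\chi^2/n\) exactly. Modal
profiles enter as supplementary rows via the transition formula
(profile × standard column coordinates) — algebraically equivalent to the
artificial-sequence route of adding a long modal sequence as an extra
observation, and exact: projecting an active row reproduces its
coordinates to machine precision.

Neighbor-joining trees are built from the modal-distance matrix
(Saitou–Nei, via ape); negative branch lengths, which NJ can produce on
non-additive data, are clamped to zero with the deficit moved to the
adjacent branch, and the count of clamped edges recorded. Topologies are
compared by the Robinson–Foulds bipartition count normalized by its
maximum \(2(n-3)\) for unrooted binary trees, so \(1 - \mathrm{RF}\)
reads directly as the fraction of shared branches.

## Pan-genome partitioning and contig triage

Cores are genes present in every chosen strain; singletons are present
only in the reference strain among the chosen set. Ancestry layers
CC1..CCn are cores over nested, progressively broader taxon sets, so
deeper layers are subsets of shallower ones. Singleton burden is reported
per 1,000 genes with box-plot summaries (median, quartiles, 1.5 × IQR
whiskers).

Plasmidome contig triage removes, in order: contigs with more than 95%
identity to the reference replicons (chromosomal/megaplasmid carry-over);
contigs with mean per-base coverage *strictly below* the cutoff — by
default the reference-contig mean + 2 SD, reflecting the much deeper
sequencing of high-copy plasmids (a contig at exactly the cutoff is
kept); and contigs of length ≤ 1,000 bp (strictly longer survive). The
kept set is provably independent of rule order; only the recorded removal
reasons depend on it.

COG composition uses explicit zeros for absent classes so profiles are
comparable across compartments, Euclidean distances, complete-linkage
clustering and PCA on the centred proportion matrix. PHELs (proteins with
highest expression levels) are the top-*n* genes of a quantitative
abundance table, ties broken by gene id; *n* defaults to 100.

## What the generator emulates — and what it does not

`simulate_genome()` builds seven gene sets of 500 genes along a
one-parameter ancestry gradient: per-family convex combinations
\((1-\alpha) U_{\mathrm{mob}} + \alpha U_{\mathrm{opt}}\) between an
AT3-leaning mobilome-like usage and a tRNA-optimal usage that
concentrates 0.85 of each family's mass on its max-weight codon. The
synthetic tRNA pool is constructed so each family's optimal codon is
G/C-ending; m-tAI, GC3 and ancestry therefore rise together *by
construction*, mirroring the mechanism rather than any species' numbers.
Gene lengths are normal (mean 300, SD 60 codons) truncated at 100 codons
— below that the per-gene chi-square match test loses validity. Amino
acids are i.i.d. from a typical GC-rich-bacterium proteome composition;
one consequence worth keeping in mind is that rare amino acids (Cys ~1%)
dominate the sampling noise of every usage estimate, exactly as in real
data. Ortholog, contig, COG and abundance tables are generated
cross-consistently with the gene sets, with ground truth recorded.

Genes are multinomial draws: no within-gene autocorrelation, no
amino-acid composition differences between sets, no gene-family
structure, no sequencing error, no length/usage correlation. Passing
tests on this generator therefore validate the *statistical machinery* —
estimator consistency, test calibration, metric identities, pipeline
trend recovery — not the biological claims themselves, which require real
genomes.

## Problem sizes and measured behaviour

The validation suite runs homogeneous-set recovery at 500 genes × 300
codons, mixture dominance over 100 replicates of 400/20-separated + 100
genes, test calibration over 200 same-pool trials of 100 genes × 200
codons with 200 shuffle replicates each (power over 100 trials at true
distance 1.0), and the full default bundle (7 × 500 genes). One caveat is
reported openly: at 150,000 codons per set, the per-family
Manhattan–Euclidean recovery distance of *any* unbiased estimator has a
sampling floor of ~0.06 for diffuse profiles (~0.04 for concentrated
ones) — the factor-two Manhattan convention doubles the total-variation
scale — so recovery should be judged against that floor, not against
zero. The modal estimator lands within ~10% of the floor; the pooled
estimator is the floor.

## Reproducibility

Every stochastic routine takes a seed; replicate-level routines derive
per-replicate substreams from a counter so results are invariant to
extending the replicate count; `simulate_genome()` writes byte-identical
bundles for a fixed seed. `scripts/acceptance.R --seed S --out f.json`
recomputes the headline quantities from scratch.
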