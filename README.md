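# codonscape

Statistical mapping of the synonymous codon usage landscape of a
multipartite bacterial genome.

Bacteria such as the rhizobia carry their genes on several replicons — a
chromosome, megaplasmids, chromids and a pool of accessory ("cryptic")
plasmids, the plasmidome. These compartments differ systematically in
codon usage: recently acquired genes (strain-specific singletons, mobile
plasmid genes) use AT-ending synonymous codons that sit poorly with the
cell's tRNA pool, while anciently conserved core genes have drifted toward
G/C-ending codons read efficiently by the most abundant tRNAs. `codonscape`
implements the quantitative machinery behind this picture, for anyone
analysing pan-genome gene sets:

- **Modal codon usage** of a gene set — the usage matched by the largest
  number of genes, a *mode* that is robust to minority gene pools, unlike
  the pooled average. Estimated by iterative reweighting with a per-family
  chi-square match test.
- **Distances between usages**: per-amino-acid Manhattan distances
  combined as a Euclidean norm,
  `d = sqrt( Σ_aa ( Σ_{c∈aa} |f_A(c) − f_B(c)| )² )`, with bootstrap
  uncertainty, a pooled-shuffle null, an exact permutation p-value and a
  z / Mann-Whitney comparison of replicate distributions.
- **tRNA adaptation**: codon weights `W_i = Σ_j (1 − s_ij)·tGCN_j` from
  tRNA gene copy numbers and wobble pairing efficiencies; per-gene tAI
  (geometric mean of weights) and the modal tAI (**m-tAI**) of a whole
  gene set, analytic or via a 10,000-codon artificial sequence.
- **Ordination and trees**: correspondence analysis of per-gene RSCU with
  modal profiles projected as supplementary points; neighbor-joining trees
  of modal distances; normalized Robinson–Foulds comparison of topologies.
- **Pan-genome partitioning**: cores, singletons and nested ancestry
  layers CC1..CCn from ortholog presence/absence tables; singletons per
  1,000 genes; plasmidome contig triage by identity (>95% removed),
  coverage (< reference mean + 2 SD removed) and length (≤1 kb removed);
  COG-class composition, distances, clustering and PCA; PHEL selection
  from protein abundances.
- **A seeded synthetic-genome generator** that emulates the ancestry
  gradient between a mobilome-like and a tRNA-optimal usage, with
  cross-consistent ortholog/contig/COG/abundance tables and recorded
  ground truth, so the full pipeline runs and is validated without any
  downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `06_partition.R`); running it end-to-end writes all
tables under `results/`. Its core, condensed:

```r
library(codonscape)

# synthetic multipartite genome: 7 gene sets along the ancestry gradient
bundle <- simulate_genome(sim_config(seed = 42))
counts <- bundle$counts
of_set <- function(s) counts[bundle$sets$gene_id[bundle$sets$set == s], ]

# modal usages and a distance with uncertainty + null
distance_estimate(of_set("plasmidome"), of_set("singleton"),
                  set_a = "plasmidome", set_b = "singleton",
                  n_reps = 200, seed = 421)
#> plasmidome vs singleton: d = 0.794 | boot 0.796 +/- 0.016 |
#>   null 0.104 +/- 0.017 | p_perm = 0.00498 (mann-whitney p = 4.8e-67)

# translational adaptation along the gradient
w <- codon_weights(absolute_adaptiveness(synthetic_trna_pool()))
prof <- modal_codon_usage(of_set("CC5"))$profile
modal_tai(prof, default_aa_composition(), w)
#> [1] 0.7156
```

The point distance 0.794 is the modal-usage separation between the mobile
plasmidome and the singleton set; the shuffle null (0.104 ± 0.017) says
two same-sized sets drawn from their common pool would sit ~0.1 apart by
sampling noise alone, so the observed separation is real (permutation
p = 0.005, the smallest value 200 replicates can certify). The m-tAI of
0.716 for the deepest core layer versus 0.307 for the plasmidome
(`analysis/05_adaptation.R` prints the full table) quantifies how much
better the ancestral core's codons match the tRNA pool; mean GC3 rises in
parallel from 33% to 89%, and the neighbor-joining tree of modal distances
reproduces the mobilome-to-core ladder exactly (normalized RF = 0 against
the generator's gradient ordering).

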