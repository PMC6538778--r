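# Synthetic multipartite-genome generator. Emulates the statistical
# structure the landscape analysis assumes: gene sets drawn from multinomial
# codon distributions along an "ancestry" gradient between a low-GC3
# mobilome-like usage and a tRNA-optimal, G/C-ending usage, plus matching
# ortholog, contig, COG and protein-abundance tables. Everything is seeded
# and deterministic so tests and the acceptance script are reproducible.

#' Typical bacterial amino-acid composition
#'
#' Rounded proteome-wide amino-acid frequencies of a GC-rich bacterium,
#' used as the default translated composition of simulated genes and
#' artificial modal sequences.
#'
#' @return Named frequency vector over the 20 amino acids (sums to 1).
#' @export
default_aa_composition <- function() {
  comp <- c(A = 0.106, R = 0.062, N = 0.033, D = 0.055, C = 0.009,
            Q = 0.036, E = 0.061, G = 0.081, H = 0.020, I = 0.055,
            L = 0.100, K = 0.042, M = 0.023, F = 0.040, P = 0.049,
            S = 0.057, T = 0.053, W = 0.013, Y = 0.026, V = 0.079)
  comp / sum(comp)
}

#' Synthetic tRNA gene pool
#'
#' A compact pool in which, for every multi-codon amino-acid family, the
#' Watson-Crick anticodon of one G/C-ending codon carries most gene copies
#' (tGCN 4) and the anticodon of one A/T-ending codon carries a single
#' copy; ATG and TGG get their cognate anticodons. With the default wobble
#' rules this makes the G/C-ending codon of each family the max-weight
#' codon, so translational optimality and GC3 rise together — the mechanism
#' the ancestry gradient models. Synthetic: not the tRNA complement of any
#' real organism.
#'
#' @return Named integer vector anticodon -> copy number.
#' @export
synthetic_trna_pool <- function() {
  cd <- .code()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    paste0(comp[b[3]], comp[b[2]], comp[b[1]])
  }
  pool <- integer(0)
  for (aa in cd$families) {
    codons <- cd$syn59[cd$syn_aa == aa]
    third <- substr(codons, 3L, 3L)
    major <- codons[order(!(third %in% c("C", "G")), codons)][1L]
    minor <- codons[order(third %in% c("C", "G"), codons)][1L]
    pool[revcomp(major)] <- max(pool[revcomp(major)], 4L, na.rm = TRUE)
    if (minor != major)
      pool[revcomp(minor)] <- max(pool[revcomp(minor)], 1L, na.rm = TRUE)
  }
  pool["CAT"] <- max(pool["CAT"], 2L, na.rm = TRUE)  # reads ATG
  pool["CCA"] <- max(pool["CCA"], 1L, na.rm = TRUE)  # reads TGG
  pool[order(names(pool))]
}

#' Mobilome-like usage profile
#'
#' An AT3-leaning profile: within each family, 0.7 of the mass is spread
#' over the A/T-ending codons and 0.3 over the G/C-ending ones (families
#' lacking one class fall back to uniform within the other).
#'
#' @return A `usage_profile`.
#' @export
mobilome_usage <- function() {
  cd <- .code()
  f <- numeric(59L); names(f) <- cd$syn59
  for (aa in cd$families) {
    idx <- which(cd$syn_aa == aa)
    at <- !cd$third_gc_syn[idx]
    w <- numeric(length(idx))
    if (any(at)) w[at] <- 0.7 / sum(at)
    if (any(!at)) w[!at] <- 0.3 / sum(!at)
    f[idx] <- w / sum(w)
  }
  structure(f, label = "U_mob", n_genes = NA_integer_,
            class = "usage_profile")
}

#' tRNA-optimal usage profile
#'
#' Within each family, mass 0.85 on the codon with the highest tAI weight
#' under the given pool and rules, 0.15 spread over the rest — the
#' high-GC3, translationally optimal end of the ancestry gradient.
#'
#' @param pool tRNA pool ([synthetic_trna_pool()] by default).
#' @param rules wobble rules ([default_wobble_rules()] by default).
#' @param major_mass mass on the max-weight codon (default 0.85).
#' @return A `usage_profile`.
#' @export
optimal_usage <- function(pool = synthetic_trna_pool(),
                          rules = default_wobble_rules(),
                          major_mass = 0.85) {
  cd <- .code()
  w <- codon_weights(absolute_adaptiveness(pool, rules))$w
  f <- numeric(59L); names(f) <- cd$syn59
  for (aa in cd$families) {
    idx <- which(cd$syn_aa == aa)
    best <- idx[which.max(w[cd$syn59[idx]])]
    f[idx] <- (1 - major_mass) / (length(idx) - 1L)
    f[best] <- major_mass
  }
  structure(f, label = "U_opt", n_genes = NA_integer_,
            class = "usage_profile")
}

#' Interpolate along the ancestry gradient
#'
#' Per-family convex combination `(1 - alpha) * U_mob + alpha * U_opt`,
#' renormalised within each family. `alpha = 0` is the mobilome-like end,
#' `alpha = 1` the tRNA-optimal end.
#'
#' @param alpha ancestry coordinate in `[0, 1]`.
#' @param u_mob,u_opt end-point `usage_profile`s.
#' @return A `usage_profile`.
#' @export
make_usage <- function(alpha, u_mob = mobilome_usage(),
                       u_opt = optimal_usage()) {
  stopifnot(alpha >= 0, alpha <= 1)
  f <- (1 - alpha) * as.numeric(u_mob) + alpha * as.numeric(u_opt)
  names(f) <- .code()$syn59
  structure(.profile_vec_renorm(f), names = .code()$syn59,
            label = sprintf("alpha=%.3g", alpha), n_genes = NA_integer_,
            class = "usage_profile")
}

#' Simulate one coding gene
#'
#' A leading ATG, `n_codons - 1` codons whose amino acids are i.i.d. from
#' `aa_composition` and whose synonymous codons follow `profile`, and a
#' trailing TAA. The realised codon counts (which [count_codons()] of the
#' sequence reproduces exactly) are returned as ground truth.
#'
#' @param profile a `usage_profile`.
#' @param n_codons total counted codons including the leading ATG.
#' @param aa_composition amino-acid frequencies (default
#'   [default_aa_composition()] without M handled specially — M and W mass
#'   yields ATG/TGG codons).
#' @param seed optional integer seed.
#' @return List: `seq` (character CDS), `counts` (`codon_counts`).
#' @export
simulate_gene <- function(profile, n_codons = 300L,
                          aa_composition = default_aa_composition(),
                          seed = NULL) {
  stopifnot(n_codons >= 2L)
  body <- modal_sequence(profile, aa_composition, n_codons - 1L, seed)
  s <- paste0("ATG", body, "TAA")
  counts <- count_codons(s)
  list(seq = s, counts = counts)
}

#' Simulate gene codon counts directly
#'
#' Count-level equivalent of [simulate_gene()]: per gene, amino-acid counts
#' are multinomial in `aa_composition` and within-family codon counts
#' multinomial in `profile`, skipping sequence assembly. The distribution
#' of the returned counts matches `count_codons(simulate_gene(...)$seq)`
#' up to the leading ATG, making it the fast generator for resampling
#' studies that need thousands of gene sets.
#'
#' @param profile a `usage_profile`.
#' @param n_genes number of genes.
#' @param n_codons codons per gene (scalar or per-gene vector).
#' @param aa_composition amino-acid frequencies.
#' @param seed optional integer seed.
#' @return Integer matrix, genes x 61.
#' @export
simulate_counts_matrix <- function(profile, n_genes, n_codons = 300L,
                                   aa_composition = default_aa_composition(),
                                   seed = NULL) {
  cd <- .code()
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  comp <- aa_composition[aa_composition > 0]
  comp <- comp / sum(comp)
  n_codons <- rep_len(as.integer(n_codons), n_genes)
  aas <- names(comp)
  m <- matrix(0L, n_genes, 61L, dimnames = list(NULL, cd$sense61))
  f <- as.numeric(profile)
  # per-gene amino-acid totals, then per-family codon splits
  aa_counts <- vapply(seq_len(n_genes), function(g)
    stats::rmultinom(1L, n_codons[g], comp)[, 1L], integer(length(comp)))
  if ("M" %in% aas) m[, "ATG"] <- aa_counts[match("M", aas), ]
  if ("W" %in% aas) m[, "TGG"] <- aa_counts[match("W", aas), ]
  for (aa in intersect(aas, cd$families)) {
    idx <- which(cd$syn_aa == aa)
    pr <- f[idx]; pr[is.na(pr)] <- 0
    if (sum(pr) == 0)
      stop("amino acid ", aa, " has zero profile mass but nonzero composition")
    tot <- aa_counts[match(aa, aas), ]
    draws <- vapply(tot, function(n)
      stats::rmultinom(1L, n, pr)[, 1L], integer(length(idx)))
    m[, cd$syn59[idx]] <- t(draws)
  }
  m
}

#' Configuration for the synthetic genome
#'
#' Defaults define the study conditions of the whole pipeline: seven gene
#' sets along the ancestry gradient — a plasmidome-like mobile set
#' (`alpha = 0`), a singleton set just above it, and five nested
#' chromosomal core layers CC1..CC5 of increasing ancestry — each of 500
#' genes whose lengths are normal (mean 300, SD 60 codons) truncated at 100
#' codons (below which the per-gene G-test loses validity); plus matching
#' ortholog, contig, COG and abundance tables.
#'
#' @param seed master integer seed.
#' @param genes_per_set genes in each set (default 500).
#' @param alphas named ancestry coordinates per set (defaults above).
#' @param codon_mean,codon_sd,codon_min gene-length distribution (codons).
#' @param n_plasmid_contigs,n_ref_contigs contig-table sizes (defaults 300
#'   true-plasmid + 60 contaminant contigs vs 40 reference contigs).
#' @param n_phel genes marked as highest-expression (PHEL) ground truth.
#' @param trna_pool,wobble,u_mob,u_opt,aa_composition model inputs, with
#'   the package defaults.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L, genes_per_set = 500L,
                       alphas = c(plasmidome = 0, singleton = 0.15,
                                  CC1 = 0.3, CC2 = 0.45, CC3 = 0.6,
                                  CC4 = 0.8, CC5 = 1),
                       codon_mean = 300, codon_sd = 60, codon_min = 100L,
                       n_plasmid_contigs = 300L, n_ref_contigs = 40L,
                       n_phel = 100L,
                       trna_pool = synthetic_trna_pool(),
                       wobble = default_wobble_rules(),
                       u_mob = mobilome_usage(), u_opt = NULL,
                       aa_composition = default_aa_composition()) {
  if (is.null(u_opt)) u_opt <- optimal_usage(trna_pool, wobble)
  stopifnot(all(alphas >= 0 & alphas <= 1), genes_per_set >= 1L)
  if (is.null(names(alphas))) names(alphas) <- paste0("set", seq_along(alphas))
  structure(list(seed = as.integer(seed), genes_per_set = genes_per_set,
                 alphas = alphas, codon_mean = codon_mean,
                 codon_sd = codon_sd, codon_min = codon_min,
                 n_plasmid_contigs = n_plasmid_contigs,
                 n_ref_contigs = n_ref_contigs, n_phel = n_phel,
                 trna_pool = trna_pool, wobble = wobble,
                 u_mob = u_mob, u_opt = u_opt,
                 aa_composition = aa_composition),
            class = "sim_config")
}

#' Simulate the synthetic multipartite genome bundle
#'
#' Generates, deterministically under `config$seed`:
#' \itemize{
#'   \item `genes`: named character vector of CDS (FASTA-writable), one per
#'     gene across all sets;
#'   \item `counts`: genes x 61 realised codon-count matrix (ground truth);
#'   \item `sets`: data frame `gene_id`, `set`;
#'   \item `orthologs`: presence/absence table over a reference strain,
#'     five conspecific strains (`S1..S5`, reference `S1`) and ten nested
#'     outgroup taxa (`T1..T10`) arranged so [ancestry_cores()] recovers
#'     CC layers of non-increasing size and singletons are reference-only;
#'   \item `contigs`: contig table mixing true plasmid contigs (deep
#'     coverage, low identity) with reference carry-over (shallow coverage
#'     and/or high identity), plus `ref_coverages` for the auto cutoff;
#'   \item `cogs`: per-gene COG class assignments with replicon-biased
#'     class frequencies;
#'   \item `abundance`: log-normal protein abundances with the PHEL ground
#'     truth forced into the most ancestral set;
#'   \item `truth`: list of every generating parameter (alphas, profiles,
#'     coverage cutoff, PHEL ids) sufficient to recompute expectations.
#' }
#'
#' @param config a [sim_config()].
#' @return A `sim_bundle` list as above.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  cd <- .code()
  sets <- names(config$alphas)
  n <- config$genes_per_set

  genes <- character(0); set_of <- character(0)
  counts <- NULL
  for (s in sets) {
    prof <- make_usage(config$alphas[[s]], config$u_mob, config$u_opt)
    lens <- pmax(config$codon_min,
                 round(stats::rnorm(n, config$codon_mean, config$codon_sd)))
    seqs <- vapply(lens, function(L)
      simulate_gene(prof, L, config$aa_composition)$seq, character(1))
    ids <- sprintf("%s_g%04d", s, seq_len(n))
    names(seqs) <- ids
    genes <- c(genes, seqs)
    set_of <- c(set_of, stats::setNames(rep(s, n), ids))
  }
  counts <- count_codons_matrix(genes)
  sets_df <- data.frame(gene_id = names(genes), set = unname(set_of),
                        stringsAsFactors = FALSE)

  orthologs <- .sim_orthologs(sets_df, sets)
  contigs <- .sim_contigs(config)
  cogs <- .sim_cogs(sets_df)
  abund <- .sim_abundance(sets_df, sets, config$n_phel)

  truth <- list(seed = config$seed, alphas = as.list(config$alphas),
                genes_per_set = n,
                u_mob = as.numeric(config$u_mob),
                u_opt = as.numeric(config$u_opt),
                aa_composition = as.list(config$aa_composition),
                trna_pool = as.list(config$trna_pool),
                cov_threshold = contigs$truth_threshold,
                phel = abund$phel)
  structure(list(genes = genes, counts = counts, sets = sets_df,
                 orthologs = orthologs, contigs = contigs$table,
                 ref_coverages = contigs$ref_coverages,
                 cogs = cogs, abundance = abund$abundance, truth = truth),
            class = "sim_bundle")
}

# ortholog table: strains S1..S5 (S1 reference), outgroup taxa T1..T10 in
# nested pairs; CCk genes present through taxon group k, singletons only in
# the reference
.sim_orthologs <- function(sets_df, sets) {
  strains <- paste0("S", 1:5)
  taxa <- paste0("T", 1:10)
  cc_sets <- grep("^CC", sets, value = TRUE)
  depth <- stats::setNames(match(cc_sets, cc_sets), cc_sets) # CC1 -> 1 ...
  m <- matrix(0L, nrow(sets_df), length(strains) + length(taxa),
              dimnames = list(NULL, c(strains, taxa)))
  m[, "S1"] <- 1L
  for (i in seq_len(nrow(sets_df))) {
    s <- sets_df$set[i]
    if (s == "singleton") next                        # reference-only
    if (s == "plasmidome") {                          # mobile: patchy
      m[i, strains[-1L]] <- stats::rbinom(4L, 1L, 0.3)
      next
    }
    m[i, strains] <- 1L                               # core within species
    k <- depth[[s]]
    if (k >= 1L) m[i, taxa[seq_len(2L * k)]] <- 1L    # nested ancestry
  }
  data.frame(gene_id = sets_df$gene_id,
             replicon = ifelse(sets_df$set == "plasmidome", "plasmidome",
                               "chromosome"),
             m, stringsAsFactors = FALSE)
}

.sim_contigs <- function(config) {
  np <- config$n_plasmid_contigs
  nc <- 60L                                     # contaminant contigs
  ref_cov <- stats::rnorm(config$n_ref_contigs, 13, 2)
  thr <- mean(ref_cov) + 2 * stats::sd(ref_cov)
  plasmid <- data.frame(
    contig_id = sprintf("plasmid_c%03d", seq_len(np)),
    length = round(stats::rlnorm(np, log(8000), 0.8)),
    coverage = stats::rlnorm(np, log(120), 0.5),
    max_identity_pct = stats::runif(np, 30, 90),
    origin = "plasmid", stringsAsFactors = FALSE)
  contam <- data.frame(
    contig_id = sprintf("contam_c%03d", seq_len(nc)),
    length = round(stats::rlnorm(nc, log(8000), 0.8)),
    coverage = stats::rnorm(nc, 13, 2),
    max_identity_pct = stats::runif(nc, 96, 100),
    origin = "reference", stringsAsFactors = FALSE)
  tab <- rbind(plasmid, contam)
  tab <- tab[order(tab$contig_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, ref_coverages = ref_cov, truth_threshold = thr)
}

.sim_cogs <- function(sets_df) {
  classes <- LETTERS[1:20]
  # mobile sets lean to L/V-type classes, core sets to metabolism-like ones
  base <- rep(1, 20)
  mob <- base; mob[c(2, 11, 12)] <- 4
  core <- base; core[c(3, 5, 7)] <- 4
  probs <- function(set) {
    p <- if (set %in% c("plasmidome", "singleton")) mob else core
    p / sum(p)
  }
  cls <- vapply(sets_df$set, function(s)
    sample(classes, 1L, prob = probs(s)), character(1))
  data.frame(gene_id = sets_df$gene_id, cog_class = cls,
             stringsAsFactors = FALSE)
}

.sim_abundance <- function(sets_df, sets, n_phel) {
  ab <- stats::rlnorm(nrow(sets_df), meanlog = 2, sdlog = 1)
  top_set <- sets[length(sets)]                 # most ancestral
  idx <- which(sets_df$set == top_set)
  phel_idx <- idx[seq_len(min(n_phel, length(idx)))]
  ab[phel_idx] <- ab[phel_idx] + stats::rlnorm(length(phel_idx), 6, 0.5)
  names(ab) <- sets_df$gene_id
  list(abundance = ab, phel = sets_df$gene_id[phel_idx])
}

#' Write a simulated bundle to disk
#'
#' Writes `genes.fasta`, `sets.tsv`, `orthologs.tsv`, `contigs.tsv`,
#' `ref_coverages.tsv`, `cogs.tsv`, `abundance.tsv` and `truth.json` under
#' `dir` with fixed formatting, so the same seed yields byte-identical
#' files.
#'
#' @param bundle a `sim_bundle` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$genes),
                              file.path(dir, "genes.fasta"))
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$sets, "sets.tsv")
  wt(bundle$orthologs, "orthologs.tsv")
  ct <- bundle$contigs
  ct$coverage <- round(ct$coverage, 4)
  ct$max_identity_pct <- round(ct$max_identity_pct, 4)
  wt(ct, "contigs.tsv")
  wt(data.frame(coverage = round(bundle$ref_coverages, 4)),
     "ref_coverages.tsv")
  wt(bundle$cogs, "cogs.tsv")
  wt(data.frame(gene_id = names(bundle$abundance),
                abundance = round(bundle$abundance, 6)), "abundance.tsv")
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
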