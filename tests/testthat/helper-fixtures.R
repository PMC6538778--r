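# Shared fixtures: count vectors, small simulated gene sets, toy trees.

zero_counts <- function() {
  structure(integer(61L), names = sense_codons(), class = "codon_counts")
}

counts_of <- function(...) {
  # counts_of(AAA = 3, AAG = 1)
  vals <- c(...)
  cc <- zero_counts()
  cc[names(vals)] <- as.integer(vals)
  attr(cc, "n_codons") <- sum(cc)
  cc
}

# genes x 61 count matrix simulated from a profile
sim_counts <- function(profile, n_genes, n_codons = 300L, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_genes), function(i)
    simulate_gene(profile, n_codons)$seq, character(1))
  count_codons_matrix(seqs)
}

# random unrooted binary tree on n leaves
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
}

# independent bipartition enumeration for the RF oracle: for every internal
# edge, the set of leaves below it, canonicalised as the side containing t1
tree_splits <- function(tr) {
  n <- length(tr$tip.label)
  splits <- list()
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    if (child <= n) next
    # leaves reachable from child moving away from the parent
    below <- c()
    stack <- child
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      kids <- tr$edge[tr$edge[, 1L] == v, 2L]
      below <- c(below, kids[kids <= n])
      stack <- c(stack, kids[kids > n])
    }
    labs <- sort(tr$tip.label[below])
    if (length(labs) < 2L || length(labs) > n - 2L) next
    # canonicalise on the side containing the alphabetically first leaf,
    # so keys are comparable across trees
    anchor <- min(tr$tip.label)
    other <- sort(setdiff(tr$tip.label, labs))
    key <- if (anchor %in% labs) paste(labs, collapse = "|")
           else paste(other, collapse = "|")
    splits[[key]] <- TRUE
  }
  names(splits)
}

brute_rf <- function(t1, t2) {
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
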