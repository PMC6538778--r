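# Pan-genome partitioning: cores, singletons and nested ancestry layers
# from ortholog presence/absence tables; singleton densities; plasmidome
# contig triage; COG-profile composition, distances and clustering; PHEL
# selection from a protein abundance table.

.presence_matrix <- function(table, strains) {
  m <- as.matrix(table[, strains, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m != 0L & m != 1L))
    stop("presence/absence cells must be 0/1")
  m
}

#' Core genes and singletons of an ortholog table
#'
#' Core genes are present in every chosen strain; singletons are present
#' only in the reference strain among the chosen strains. Computed per
#' replicon when the table carries a `replicon` column.
#'
#' @param table data frame with `gene_id`, optional `replicon`, and one 0/1
#'   presence column per strain. The reference strain's column must be
#'   all-present.
#' @param strains character vector of strain columns to analyse (must
#'   include `reference`).
#' @param reference name of the reference strain column.
#' @return List with `core` and `singleton` gene-id vectors, plus
#'   `by_replicon` (same split per replicon label) when available.
#' @export
core_and_singletons <- function(table, strains, reference = strains[[1L]]) {
  if (length(strains) == 0L) stop("empty strain set")
  stopifnot(all(strains %in% names(table)), reference %in% strains)
  m <- .presence_matrix(table, strains)
  if (any(m[, reference] != 1L))
    stop("reference strain column must be all-present")
  core <- rowSums(m) == length(strains)
  singleton <- rowSums(m) == 1L         # only the reference carries it
  ids <- table$gene_id
  out <- list(core = ids[core], singleton = ids[singleton])
  if ("replicon" %in% names(table)) {
    out$by_replicon <- lapply(split(seq_along(ids), table$replicon),
                              function(i) list(core = ids[i][core[i]],
                                               singleton = ids[i][singleton[i]]))
  }
  out
}

#' Nested ancestry core layers
#'
#' Given nested taxon sets `T1 <= T2 <= ... <= Tn`, layer `CCk` holds the
#' reference genes present in every taxon of `Tk`; deeper layers are
#' subsets of shallower ones (`CC(k+1)` within `CCk`).
#'
#' @param table ortholog data frame (`gene_id` + 0/1 taxon columns).
#' @param scheme ordered list of character vectors of taxon columns; each
#'   must contain the previous (nesting is checked).
#' @return Named list `CC1..CCn` of gene-id vectors, sizes non-increasing.
#' @export
ancestry_cores <- function(table, scheme) {
  if (length(scheme) == 0L) stop("empty ancestry scheme")
  for (k in seq_along(scheme)[-1L]) {
    if (!all(scheme[[k - 1L]] %in% scheme[[k]]))
      stop("ancestry scheme is not nested at level ", k)
  }
  ids <- table$gene_id
  out <- lapply(scheme, function(taxa) {
    m <- .presence_matrix(table, taxa)
    ids[rowSums(m) == length(taxa)]
  })
  names(out) <- if (!is.null(names(scheme))) names(scheme)
                else paste0("CC", seq_along(scheme))
  out
}

#' Singletons per 1,000 genes
#'
#' @param n_singletons,n_genes counts (vectorised).
#' @return `1000 * n_singletons / n_genes`.
#' @export
singleton_density <- function(n_singletons, n_genes) {
  if (any(n_genes <= 0)) stop("n_genes must be positive")
  1000 * n_singletons / n_genes
}

#' Box-plot summary of per-strain densities
#'
#' Median, quartiles and whiskers at the most extreme values within
#' 1.5 x IQR of the quartiles.
#'
#' @param values numeric vector (e.g. per-strain singleton densities).
#' @return Named vector: `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`.
#' @export
density_box_stats <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(values[values >= q[1] - 1.5 * iqr])
  hi <- max(values[values <= q[3] + 1.5 * iqr])
  c(lower_whisker = lo, q1 = q[1], median = q[2], q3 = q[3],
    upper_whisker = hi)
}

#' Triage plasmidome contigs by identity, coverage and length
#'
#' Removes, in order: contigs with more than `max_identity` percent
#' identity to the reference replicons (chromosome/megaplasmid
#' contamination); contigs with mean per-base coverage strictly below the
#' threshold (plasmids run much deeper than the chromosome, so low coverage
#' marks reference carry-over) — with `cov_threshold = "auto"` the cutoff is
#' `mean(ref_coverages) + 2 * sd(ref_coverages)`; and contigs of length
#' `<= min_len`. The kept set is independent of the filter order.
#'
#' @param contigs data frame with `contig_id`, `length`, `coverage`,
#'   `max_identity_pct`.
#' @param min_len keep only contigs strictly longer than this (bp).
#' @param max_identity remove contigs with identity strictly above this (%).
#' @param cov_threshold numeric coverage cutoff (kept if `coverage >=`
#'   threshold) or `"auto"`.
#' @param ref_coverages numeric coverages of reference-replicon contigs
#'   (needed for `"auto"`; at least 2).
#' @return List: `kept` (data frame, input order), `removed` (data frame
#'   with a `reason` column), `cov_threshold` used.
#' @export
filter_plasmid_contigs <- function(contigs, min_len = 1000, max_identity = 95,
                                   cov_threshold = "auto",
                                   ref_coverages = NULL) {
  stopifnot(all(c("contig_id", "length", "coverage", "max_identity_pct")
                %in% names(contigs)))
  if (nrow(contigs) == 0L) stop("no contigs")
  if (identical(cov_threshold, "auto")) {
    if (is.null(ref_coverages) || length(ref_coverages) < 2L)
      stop("auto coverage threshold needs >= 2 reference contig coverages")
    cov_threshold <- mean(ref_coverages) + 2 * stats::sd(ref_coverages)
  }
  reason <- rep(NA_character_, nrow(contigs))
  reason[is.na(reason) & contigs$max_identity_pct > max_identity] <-
    "high-identity"
  reason[is.na(reason) & contigs$coverage < cov_threshold] <- "low-coverage"
  reason[is.na(reason) & contigs$length <= min_len] <- "short"
  keep <- is.na(reason)
  list(kept = contigs[keep, , drop = FALSE],
       removed = cbind(contigs[!keep, , drop = FALSE],
                       reason = reason[!keep]),
       cov_threshold = cov_threshold)
}

#' COG class proportions of a gene set
#'
#' @param assignments named character vector: gene_id -> COG class letter.
#'   Genes with `NA`/empty class are excluded from the denominator (their
#'   number is recorded in the `unassigned` attribute).
#' @param classes class universe (default `LETTERS`); classes with zero
#'   counts are kept as explicit zeros so profiles are comparable.
#' @param label optional source label.
#' @return Named proportion vector of class `cog_profile`, summing to 1.
#' @export
cog_proportions <- function(assignments, classes = LETTERS, label = NULL) {
  cls <- assignments[!is.na(assignments) & nzchar(assignments)]
  if (length(cls) == 0L) stop("no assigned genes")
  if (any(!cls %in% classes))
    stop("assignment outside the class universe: ",
         paste(utils::head(unique(setdiff(cls, classes))), collapse = ","))
  tab <- table(factor(cls, levels = classes))
  p <- as.numeric(tab) / length(cls)
  names(p) <- classes
  structure(p, label = label, unassigned = length(assignments) - length(cls),
            class = "cog_profile")
}

#' Euclidean distance between two COG profiles
#'
#' @param p,q `cog_profile` vectors over the same class set.
#' @return Euclidean distance on the proportion vectors.
#' @export
cog_distance <- function(p, q) {
  if (!identical(names(p), names(q)))
    stop("profiles must be over the same class set")
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Hierarchical clustering of composition profiles
#'
#' Complete-linkage clustering on Euclidean distances between profile rows.
#'
#' @param profiles matrix (profiles x classes) or list of `cog_profile`s.
#' @param method linkage passed to [stats::hclust()] (default "complete").
#' @return An `hclust` dendrogram.
#' @export
cluster_profiles <- function(profiles, method = "complete") {
  m <- if (is.list(profiles)) do.call(rbind, lapply(profiles, as.numeric))
       else as.matrix(profiles)
  if (is.list(profiles) && !is.null(names(profiles)))
    rownames(m) <- names(profiles)
  stats::hclust(stats::dist(m), method = method)
}

#' PCA scores of composition profiles
#'
#' Principal component scores of the mean-centred profile matrix (plumbing
#' over [stats::prcomp()]).
#'
#' @param profiles matrix (profiles x classes) or list of `cog_profile`s.
#' @return Score matrix (profiles x components).
#' @export
pca_profiles <- function(profiles) {
  m <- if (is.list(profiles)) do.call(rbind, lapply(profiles, as.numeric))
       else as.matrix(profiles)
  if (is.list(profiles) && !is.null(names(profiles)))
    rownames(m) <- names(profiles)
  stats::prcomp(m, center = TRUE, scale. = FALSE)$x
}

#' Select the most highly expressed proteins (PHELs)
#'
#' The `top_n` genes by protein abundance; ties broken by gene id so the
#' selection is deterministic.
#'
#' @param abundance named numeric vector: gene_id -> abundance.
#' @param top_n how many genes to keep (default 100).
#' @return Character vector of gene ids (length `min(top_n, n)`).
#' @export
select_phel <- function(abundance, top_n = 100L) {
  if (length(abundance) == 0L) stop("empty abundance table")
  if (top_n < 1L) stop("top_n must be >= 1")
  if (top_n > length(abundance)) {
    warning("top_n exceeds available genes; returning all")
    top_n <- length(abundance)
  }
  ord <- order(-abundance, names(abundance))
  names(abundance)[ord][seq_len(top_n)]
}
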