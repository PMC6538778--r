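# Codon counting, RSCU, GC/GC3 and delta-RSCU enrichment.

.as_char_seq <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (inherits(x, "DNAString")) return(as.character(x))
  if (is.character(x)) return(toupper(x))
  stop("sequences must be character, DNAString or DNAStringSet")
}

#' Count codons of a coding sequence
#'
#' Tallies the 61 sense codons of a CDS. A trailing stop codon is excluded.
#' Codons containing non-ACGT symbols are skipped and counted in the
#' `skipped` attribute, never guessed.
#'
#' @param cds a single nucleotide sequence (character or `DNAString`).
#' @param gene_id optional identifier stored on the result.
#' @param internal_stop what to do with an internal stop codon: `"error"`
#'   (default) aborts, `"truncate"` warns and keeps only the codons before
#'   the first internal stop.
#' @return An integer vector of class `codon_counts`, length 61, named by
#'   [sense_codons()], with attributes `gene_id`, `n_codons` (sum of counts)
#'   and `skipped` (ambiguous codons dropped).
#' @examples
#' count_codons("ATGAAATAA") # ATG:1, AAA:1; terminal TAA dropped
#' @export
count_codons <- function(cds, gene_id = NULL,
                         internal_stop = c("error", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  s <- .as_char_seq(cds)
  if (length(s) != 1L) stop("count_codons() takes a single sequence")
  if (nchar(s) == 0L) stop("empty sequence")
  if (nchar(s) %% 3L != 0L)
    stop("malformed CDS: length ", nchar(s), " is not a multiple of 3")
  cod <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  cd <- .code()
  n <- length(cod)
  if (cod[n] %in% cd$stop3) cod <- cod[-n]
  is_stop <- cod %in% cd$stop3
  if (any(is_stop)) {
    if (internal_stop == "error")
      stop("internal stop codon at codon ", which(is_stop)[1L])
    warning("internal stop codon; truncating at codon ", which(is_stop)[1L])
    cod <- cod[seq_len(which(is_stop)[1L] - 1L)]
  }
  known <- cod %in% cd$sense61
  counts <- integer(61L)
  names(counts) <- cd$sense61
  tab <- table(factor(cod[known], levels = cd$sense61))
  counts[] <- as.integer(tab)
  structure(counts,
            gene_id = gene_id,
            n_codons = sum(counts),
            skipped = sum(!known),
            class = "codon_counts")
}

#' Codon-count matrix for a collection of CDS
#'
#' Vectorised companion to [count_codons()]: one row per gene, one column
#' per sense codon. Trailing stop codons are removed before counting and
#' ambiguous codons are skipped (Biostrings does the window counting).
#'
#' @param seqs `DNAStringSet` or named character vector of CDS.
#' @param internal_stop `"error"` or `"truncate"` as in [count_codons()].
#' @return Integer matrix, genes x 61, with rownames from `seqs`.
#' @export
count_codons_matrix <- function(seqs, internal_stop = c("error", "truncate")) {
  internal_stop <- match.arg(internal_stop)
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(.as_char_seq(seqs))
  cd <- .code()
  w <- Biostrings::width(seqs)
  if (any(w == 0L)) stop("empty sequence in input")
  if (any(w %% 3L != 0L))
    stop("malformed CDS (length not a multiple of 3): ",
         paste(utils::head(which(w %% 3L != 0L)), collapse = ", "))
  last <- as.character(Biostrings::subseq(seqs, start = w - 2L, end = w))
  has_stop <- last %in% cd$stop3
  if (any(has_stop))
    seqs[has_stop] <- Biostrings::subseq(seqs[has_stop], start = 1L,
                                         end = w[has_stop] - 3L)
  tri <- Biostrings::trinucleotideFrequency(seqs, step = 3L)
  stop_hits <- rowSums(tri[, cd$stop3, drop = FALSE])
  if (any(stop_hits > 0L)) {
    bad <- which(stop_hits > 0L)
    if (internal_stop == "error")
      stop("internal stop codon in sequence(s): ",
           paste(utils::head(bad), collapse = ", "))
    warning("internal stop codon(s); truncating ", length(bad), " sequence(s)")
    for (i in bad) {
      cc <- suppressWarnings(count_codons(as.character(seqs[[i]]),
                                          internal_stop = "truncate"))
      tri[i, ] <- 0L
      tri[i, cd$sense61] <- as.integer(cc)
    }
    return(.finish_count_matrix(tri, cd, seqs))
  }
  .finish_count_matrix(tri, cd, seqs)
}

.finish_count_matrix <- function(tri, cd, seqs) {
  m <- tri[, cd$sense61, drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- names(seqs)
  m
}

.counts_to_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) == 61L && !is.null(colnames(x)) &&
        all(colnames(x) == .code()$sense61)) return(x)
    stop("count matrix must have the 61 sense-codon columns in order")
  }
  if (inherits(x, "codon_counts")) return(matrix(x, 1L, 61L,
    dimnames = list(attr(x, "gene_id"), names(x))))
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty gene list")
    m <- do.call(rbind, lapply(x, function(cc) as.integer(cc)))
    colnames(m) <- .code()$sense61
    rownames(m) <- vapply(x, function(cc) {
      id <- attr(cc, "gene_id"); if (is.null(id)) NA_character_ else id
    }, character(1))
    if (all(is.na(rownames(m)))) rownames(m) <- NULL
    return(m)
  }
  stop("cannot interpret codon counts input")
}

#' Relative synonymous codon usage
#'
#' RSCU of a gene (or pooled set): the observed codon count divided by the
#' count expected if all synonyms of its amino acid were used equally,
#' `count(c) / (T_aa / k_aa)`. Families with zero total are returned as `NA`
#' (missing, not zero) unless a pseudocount is supplied.
#'
#' @param counts a `codon_counts` vector, a 61-long named count vector, or a
#'   pooled count matrix row-summed beforehand.
#' @param pseudocount non-negative value added to every codon count before
#'   computing (default 0).
#' @return Numeric vector of class `rscu` over [syn_codons()]; fully observed
#'   families sum to their number of synonyms.
#' @export
rscu <- function(counts, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  cd <- .code()
  if (is.matrix(counts)) counts <- colSums(counts)
  cnt <- as.numeric(counts[cd$syn59]) + pseudocount
  if (anyNA(cnt)) stop("counts must cover the 59 degenerate codons")
  fam_tot <- as.numeric(crossprod(cd$fam_ind, cnt))       # per family
  k <- cd$fam_sizes
  expd <- (fam_tot / k)[match(cd$syn_aa, cd$families)]
  out <- ifelse(expd > 0, cnt / expd, NA_real_)
  names(out) <- cd$syn59
  structure(out, class = "rscu")
}

#' Per-gene RSCU matrix
#'
#' RSCU for every row of a codon-count matrix. Genes lacking an entire
#' amino-acid family get `0` for that family's codons when `impute_zero` is
#' `TRUE` (the behaviour correspondence analysis needs: complete rows); the
#' affected genes are flagged in the `imputed_genes` attribute.
#'
#' @param counts_matrix genes x 61 integer matrix ([count_codons_matrix()]).
#' @param impute_zero replace missing-family `NA`s by 0 (default `TRUE`).
#' @param pseudocount as in [rscu()].
#' @return Numeric matrix, genes x 59.
#' @export
rscu_matrix <- function(counts_matrix, impute_zero = TRUE, pseudocount = 0) {
  cd <- .code()
  m <- .counts_to_matrix(counts_matrix)[, cd$syn59, drop = FALSE] + pseudocount
  fam_tot <- m %*% cd$fam_ind                              # genes x 18
  k <- cd$fam_sizes
  expd <- sweep(fam_tot, 2L, k, "/")[, match(cd$syn_aa, cd$families),
                                     drop = FALSE]
  out <- m / expd
  out[expd == 0] <- NA_real_
  flagged <- which(rowSums(is.na(out)) > 0L)
  if (impute_zero) out[is.na(out)] <- 0
  colnames(out) <- cd$syn59
  attr(out, "imputed_genes") <- flagged
  out
}

#' Codon usage profile pooled from gene counts
#'
#' Pools codon counts over genes and normalises within each amino-acid
#' family, producing the within-family synonymous codon frequencies used to
#' initialise the modal search and to compare gene-set usages.
#'
#' @param counts a list of `codon_counts`, a genes x 61 matrix, or a single
#'   count vector.
#' @param label optional profile label.
#' @return Numeric vector of class `usage_profile` over [syn_codons()]; each
#'   family with nonzero mass sums to 1, zero-mass families are `NA`.
#'   Attributes: `label`, `n_genes`.
#' @export
usage_from_counts <- function(counts, label = NULL) {
  m <- .counts_to_matrix(counts)
  if (nrow(m) == 0L) stop("empty gene list")
  pooled <- colSums(m)
  .profile_from_pooled(pooled, label = label, n_genes = nrow(m))
}

.profile_from_pooled <- function(pooled, label = NULL, n_genes = NA_integer_) {
  cd <- .code()
  cnt <- as.numeric(pooled[cd$syn59])
  fam_tot <- as.numeric(crossprod(cd$fam_ind, cnt))
  denom <- fam_tot[match(cd$syn_aa, cd$families)]
  f <- ifelse(denom > 0, cnt / denom, NA_real_)
  names(f) <- cd$syn59
  structure(f, label = label, n_genes = as.integer(n_genes),
            class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat("usage_profile", if (!is.null(lab)) paste0("'", lab, "'"),
      "over 59 codons;", sum(is.na(x)), "missing\n")
  print(unclass(round(x, 4)))
  invisible(x)
}

#' GC content
#'
#' Percent G+C over A/C/G/T characters; ambiguous symbols are ignored.
#'
#' @param seqs one or more sequences (character or `DNAStringSet`).
#' @param per_sequence if `TRUE` return the unweighted mean of per-sequence
#'   GC percentages; default pools all sequences (base-weighted).
#' @return GC percent (0-100).
#' @export
gc_content <- function(seqs, per_sequence = FALSE) {
  s <- .as_char_seq(seqs)
  if (length(s) == 0L) stop("no sequences")
  xss <- Biostrings::DNAStringSet(s)
  fr <- Biostrings::alphabetFrequency(xss)[, c("A", "C", "G", "T"),
                                           drop = FALSE]
  tot <- rowSums(fr)
  gcs <- rowSums(fr[, c("G", "C"), drop = FALSE])
  if (per_sequence) {
    if (any(tot == 0)) stop("sequence with no unambiguous bases")
    return(mean(100 * gcs / tot))
  }
  if (sum(tot) == 0) stop("no unambiguous bases in input")
  100 * sum(gcs) / sum(tot)
}

#' GC content at the third codon position (GC3)
#'
#' Percent of counted codons whose third base is G or C. The default scope
#' includes all 61 sense codons (ATG and TGG contribute fixed third bases);
#' `scope = "syn"` restricts to the 59 synonymously degenerate codons.
#'
#' @param counts a `codon_counts` vector, genes x 61 matrix, or list thereof.
#' @param scope `"sense"` (default) or `"syn"`.
#' @return For a single gene, the GC3 percent. For a matrix/list, a list with
#'   `per_gene` (vector), `mean` and `sd`.
#' @export
gc3 <- function(counts, scope = c("sense", "syn")) {
  scope <- match.arg(scope)
  cd <- .code()
  single <- inherits(counts, "codon_counts") ||
    (!is.matrix(counts) && !is.list(counts) && length(counts) == 61L)
  m <- .counts_to_matrix(if (single) structure(as.integer(counts),
    names = cd$sense61, class = "codon_counts") else counts)
  if (scope == "sense") {
    sel <- rep(TRUE, 61L); gcmask <- cd$third_gc_sense
  } else {
    sel <- colnames(m) %in% cd$syn59; gcmask <- cd$third_gc_sense[sel]
  }
  sub <- m[, sel, drop = FALSE]
  tot <- rowSums(sub)
  if (any(tot == 0)) stop("gene with zero counted codons")
  pg <- 100 * as.numeric(sub %*% gcmask) / tot
  names(pg) <- rownames(m)
  if (single) return(pg[[1L]])
  list(per_gene = pg, mean = mean(pg), sd = stats::sd(pg))
}

#' Codon enrichment between two RSCU vectors
#'
#' Elementwise difference `rscu_a - rscu_b` over the 59 degenerate codons
#' (e.g. a deep ancestry layer minus the within-species core, so positive
#' values mark codons enriched with ancestry). Missing families propagate
#' `NA`.
#'
#' @param rscu_a,rscu_b `rscu` vectors over [syn_codons()].
#' @return Named numeric vector over [syn_codons()].
#' @export
delta_rscu <- function(rscu_a, rscu_b) {
  cd <- .code()
  if (!identical(names(rscu_a), cd$syn59) ||
      !identical(names(rscu_b), cd$syn59))
    stop("both RSCU vectors must be indexed by the 59 degenerate codons")
  out <- as.numeric(rscu_a) - as.numeric(rscu_b)
  names(out) <- cd$syn59
  out
}
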