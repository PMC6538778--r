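# Modal codon usage: the synonymous usage matched by the largest number of
# genes in a set, estimated by iteratively reweighting genes with a
# per-amino-acid-family G-test against the current profile. Unlike the
# pooled (average) usage, the mode is robust to a minority gene pool with a
# divergent usage — the property the whole landscape analysis leans on.

.FLOOR <- 1e-4

# floor the within-family frequencies so observed codons never meet zero
# expectation; entries already above the floor are untouched unless their
# family needs renormalising (so an exactly-matching gene still gets G = 0)
.floor_profile <- function(f) {
  cd <- .code()
  f[is.na(f)] <- 1 / cd$fam_sizes[match(cd$syn_aa, cd$families)][is.na(f)]
  low <- f < .FLOOR
  if (!any(low)) return(f)
  f[low] <- .FLOOR
  denom <- as.numeric(crossprod(cd$fam_ind, f))[match(cd$syn_aa, cd$families)]
  f / denom
}

# vectorised per-gene chi-square match p-values; syn_mat genes x 59,
# fam_tot genes x 18. Pearson's X^2 accumulated over the families present
# in each gene; chosen over the likelihood-ratio G because its null mean is
# exactly the df even at the small per-family expected counts typical of a
# 300-codon gene, giving near-uniform p-values (see the methods vignette).
.match_pvalues <- function(syn_mat, fam_tot, prof_floored) {
  cd <- .code()
  expd <- fam_tot[, match(cd$syn_aa, cd$families), drop = FALSE] *
    rep(prof_floored, each = nrow(syn_mat))
  cell <- (syn_mat - expd)^2 / expd
  cell[expd == 0] <- 0
  X2 <- rowSums(cell)
  df <- as.numeric((fam_tot > 0) %*% (cd$fam_sizes - 1L))
  p <- stats::pchisq(X2, df, lower.tail = FALSE)
  p[df == 0] <- 1
  p
}

#' G-test p-value for a gene matching a usage profile
#'
#' Tests whether a gene's synonymous codon counts look like a multinomial
#' draw from a usage profile. Within each amino-acid family present in the
#' gene Pearson's statistic `sum((obs - exp)^2 / exp)` is accumulated and
#' the total referred to a chi-square with `sum(k_aa - 1)` degrees of
#' freedom over those families (Pearson's form keeps the null mean exactly
#' at the df even for the small per-family counts of a typical gene, so
#' p-values stay near-uniform). Profile frequencies are floored at `1e-4`
#' (and renormalised) so observed codons never meet zero expectation.
#'
#' @param counts a `codon_counts` vector (or 61-long named counts).
#' @param profile a `usage_profile`.
#' @return p-value in `[0, 1]`; genes whose counts equal expectation give 1.
#' @export
gene_match_pvalue <- function(counts, profile) {
  cd <- .code()
  m <- .counts_to_matrix(counts)[, cd$syn59, drop = FALSE]
  storage.mode(m) <- "double"
  if (sum(m) == 0) stop("gene has no informative (degenerate-family) codons")
  fam_tot <- m %*% cd$fam_ind
  .match_pvalues(m, fam_tot, .floor_profile(as.numeric(profile)))[[1L]]
}

# core fitting loop on a genes x 61 count matrix
.modal_fit <- function(mat, p_threshold = 0.1, max_iter = 100L, tol = 1e-6,
                       min_codons = 50L,
                       weighting = c("saturating", "pvalue")) {
  weighting <- match.arg(weighting)
  cd <- .code()
  syn_mat <- mat[, cd$syn59, drop = FALSE]
  storage.mode(syn_mat) <- "double"
  fam_tot <- syn_mat %*% cd$fam_ind
  pooled <- colSums(syn_mat)
  prof <- .profile_vec(pooled)
  small <- rowSums(syn_mat) < min_codons
  p <- rep(1, nrow(mat))
  converged <- FALSE
  prev <- prof
  prev_delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- .match_pvalues(syn_mat, fam_tot, .floor_profile(prof))
    w <- if (weighting == "saturating") pmin(1, p / p_threshold) else p
    if (sum(w) == 0) w <- rep(1, length(w))
    newprof <- .profile_vec(as.numeric(crossprod(syn_mat, w)))
    ok <- !is.na(newprof) & !is.na(prof)
    delta <- sum(abs(newprof[ok] - prof[ok]))
    if (delta < tol) {
      prof <- newprof
      converged <- TRUE
      break
    }
    # period-2 oscillation: successive L1 changes stall pairwise
    if (it >= 3L && abs(delta - prev_delta) < tol * 1e-2 && delta >= tol) {
      osc <- (newprof + prof) / 2
      prof <- .profile_vec_renorm(osc)
      converged <- FALSE
      break
    }
    prev_delta <- delta
    prev <- prof
    prof <- newprof
  }
  list(freqs = prof, pvalues = p, n_iterations = it, converged = converged,
       flagged_small = which(small))
}

.profile_vec <- function(pooled59) {
  cd <- .code()
  denom <- as.numeric(crossprod(cd$fam_ind, pooled59))[
    match(cd$syn_aa, cd$families)]
  ifelse(denom > 0, pooled59 / denom, NA_real_)
}

.profile_vec_renorm <- function(f) {
  cd <- .code()
  f[f < 0] <- 0
  .profile_vec(ifelse(is.na(f), 0, f))
}

#' Modal codon usage of a gene set
#'
#' Estimates the usage profile matched by the largest number of genes.
#' Starting from the pooled usage, genes are reweighted each iteration by
#' their [gene_match_pvalue()] against the current profile and the profile
#' recomputed as the weighted pooled usage; genes from a minority pool with
#' a divergent usage receive vanishing weights, so the estimate tracks the
#' dominant component rather than the average.
#'
#' The default `"saturating"` weighting gives every gene matching at the
#' threshold full weight, `w = min(1, p / p_threshold)`: on a homogeneous
#' set nearly all genes carry weight 1 and the modal estimate keeps the
#' pooled (maximum-likelihood) estimator's efficiency, while genes from a
#' divergent minority still fade to zero. `"pvalue"` weights genes by the
#' raw p-value; it is equally mode-seeking but noisier under homogeneity,
#' because chance low p-values among matching genes feed back into the
#' profile (see the methods vignette).
#'
#' @param genes a list of `codon_counts`, or a genes x 61 count matrix.
#' @param p_threshold p-value above which a gene is counted as "matching"
#'   the modal usage; under the default weighting also the saturation point.
#' @param max_iter maximum reweighting iterations.
#' @param tol L1 convergence tolerance on the profile.
#' @param min_codons genes with fewer informative codons are flagged (the
#'   chi-square approximation is poor there) but still used.
#' @param weighting `"saturating"` (default) or `"pvalue"`.
#' @param label optional label for the returned profile.
#' @return A `modal_result` list: `profile` (a `usage_profile`),
#'   `match_pvalues`, `n_matching`, `threshold`, `n_iterations`, `converged`,
#'   `flagged_small`.
#' @export
modal_codon_usage <- function(genes, p_threshold = 0.1, max_iter = 100L,
                              tol = 1e-6, min_codons = 50L,
                              weighting = c("saturating", "pvalue"),
                              label = NULL) {
  mat <- .counts_to_matrix(genes)
  if (nrow(mat) < 1L) stop("need at least one gene")
  fit <- .modal_fit(mat, p_threshold, max_iter, tol, min_codons, weighting)
  prof <- structure(fit$freqs, names = .code()$syn59, label = label,
                    n_genes = nrow(mat), class = "usage_profile")
  structure(list(profile = prof,
                 match_pvalues = fit$pvalues,
                 n_matching = sum(fit$pvalues > p_threshold),
                 threshold = p_threshold,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged,
                 flagged_small = fit$flagged_small),
            class = "modal_result")
}

#' @export
print.modal_result <- function(x, ...) {
  cat("Modal codon usage:", length(x$match_pvalues), "genes,",
      x$n_matching, "matching at p >", x$threshold, "\n",
      x$n_iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Artificial sequence realising a usage profile
#'
#' Generates a coding sequence of `n_codons` codons whose amino acids are
#' drawn i.i.d. from `aa_composition` and whose synonymous codon for each
#' amino acid is drawn from `profile` — preserving both the codon usage and
#' the translated composition, as needed to evaluate the modal tRNA
#' adaptation index of a gene set on a long (default 10,000 codon) sequence.
#'
#' @param profile a `usage_profile` over [syn_codons()].
#' @param aa_composition named frequencies over one-letter amino-acid codes
#'   (may include M and W; stop never). Normalised internally.
#' @param n_codons number of codons to emit (default 10000).
#' @param seed integer seed; same seed, same sequence.
#' @return A single character string of length `3 * n_codons`.
#' @export
modal_sequence <- function(profile, aa_composition, n_codons = 10000L,
                           seed = NULL) {
  cd <- .code()
  comp <- aa_composition[aa_composition > 0]
  if (any(!names(comp) %in% c(cd$families, "M", "W")))
    stop("unknown amino acid in composition: ",
         paste(setdiff(names(comp), c(cd$families, "M", "W")), collapse = ","))
  comp <- comp / sum(comp)
  f <- as.numeric(profile)
  for (aa in intersect(names(comp), cd$families)) {
    idx <- which(cd$syn_aa == aa)
    if (all(is.na(f[idx])) || sum(f[idx], na.rm = TRUE) == 0)
      stop("amino acid ", aa, " has zero profile mass but nonzero composition")
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  aas <- sample(names(comp), n_codons, replace = TRUE, prob = comp)
  out <- character(n_codons)
  out[aas == "M"] <- "ATG"
  out[aas == "W"] <- "TGG"
  for (aa in intersect(unique(aas), cd$families)) {
    idx <- which(cd$syn_aa == aa)
    pr <- f[idx]; pr[is.na(pr)] <- 0
    sel <- aas == aa
    out[sel] <- sample(cd$syn59[idx], sum(sel), replace = TRUE, prob = pr)
  }
  paste(out, collapse = "")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
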