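# Distances between gene-set codon usages: per-amino-acid Manhattan
# distances combined into a Euclidean distance, bootstrap uncertainty,
# pooled-shuffle null and significance machinery.

#' Distance between two usage profiles
#'
#' For each multi-codon amino acid the Manhattan distance between the
#' within-family frequencies is taken, `m_aa = sum(|f_a - f_b|)`, and the
#' per-family values combined as a Euclidean norm over the 18 families,
#' `d = sqrt(sum(m_aa^2))`. Families missing (NA) in either profile are
#' dropped pairwise and recorded in the `dropped_families` attribute.
#'
#' @param a,b `usage_profile` vectors over [syn_codons()].
#' @return Non-negative distance; at most `sqrt(72)` for fully observed
#'   profiles.
#' @export
usage_distance <- function(a, b) {
  cd <- .code()
  fa <- as.numeric(a); fb <- as.numeric(b)
  if (length(fa) != 59L || length(fb) != 59L)
    stop("profiles must be over the 59 degenerate codons")
  diffs <- abs(fa - fb)
  m <- as.numeric(crossprod(cd$fam_ind, ifelse(is.na(diffs), 0, diffs)))
  fam_na <- as.logical(crossprod(cd$fam_ind, is.na(diffs)))
  if (all(fam_na)) stop("no shared amino-acid families between profiles")
  d <- sqrt(sum(m[!fam_na]^2))
  if (any(fam_na)) attr(d, "dropped_families") <- cd$families[fam_na]
  d
}

.dist_num <- function(a, b) as.numeric(usage_distance(a, b))

#' Pairwise distance matrix of usage profiles
#'
#' @param profiles named list of `usage_profile`s (length >= 2).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(profiles) {
  n <- length(profiles)
  if (n < 2L) stop("need at least two profiles")
  labs <- names(profiles)
  if (is.null(labs)) labs <- paste0("set", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- .dist_num(profiles[[i]], profiles[[j]])
  }
  d
}

# counter-derived substream seed: changing n_reps never reshuffles earlier
# replicates; kept below 2^31
.substream_seed <- function(seed, i) {
  (as.double(seed) %% 2147483629 + i * 1664525 + 1013904223) %% 2147483629
}

.modal_profile_of <- function(mat, max_iter, tol) {
  fit <- .modal_fit(mat, max_iter = max_iter, tol = tol)
  fit$freqs
}

#' Bootstrap distribution of the modal-usage distance
#'
#' Each replicate resamples each gene set with replacement (to its own
#' size), recomputes both modal usages and their [usage_distance()].
#' Replicate `i` uses a substream derived from `seed` and `i`, so extending
#' `n_reps` never changes earlier replicates.
#'
#' @param genes_a,genes_b count matrices (genes x 61) or lists of
#'   `codon_counts`.
#' @param n_reps bootstrap replicates (default 1000, as in a full analysis).
#' @param seed master integer seed.
#' @param max_iter,tol modal-fit controls (see [modal_codon_usage()]).
#' @return List: `boot_mean`, `boot_sd`, `reps` (replicate vector).
#' @export
bootstrap_distance <- function(genes_a, genes_b, n_reps = 1000L, seed = 1L,
                               max_iter = 100L, tol = 1e-6) {
  ma <- .counts_to_matrix(genes_a); mb <- .counts_to_matrix(genes_b)
  if (nrow(ma) < 1L || nrow(mb) < 1L) stop("both gene sets must be non-empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  reps <- vapply(seq_len(n_reps), function(i) {
    set.seed(.substream_seed(seed, i))
    ia <- sample.int(nrow(ma), replace = TRUE)
    ib <- sample.int(nrow(mb), replace = TRUE)
    pa <- .modal_profile_of(ma[ia, , drop = FALSE], max_iter, tol)
    pb <- .modal_profile_of(mb[ib, , drop = FALSE], max_iter, tol)
    .dist_num(pa, pb)
  }, numeric(1))
  list(boot_mean = mean(reps), boot_sd = stats::sd(reps), reps = reps)
}

#' Pooled-shuffle null distribution of the modal-usage distance
#'
#' Each replicate pools the two gene sets, partitions the pool at random
#' (without replacement) into two new sets of the original sizes, and
#' recomputes the modal-usage distance — the distribution expected if A and
#' B were drawn from one common gene pool.
#'
#' @inheritParams bootstrap_distance
#' @return List: `null_mean`, `null_sd`, `reps`.
#' @export
shuffled_null <- function(genes_a, genes_b, n_reps = 1000L, seed = 1L,
                          max_iter = 100L, tol = 1e-6) {
  ma <- .counts_to_matrix(genes_a); mb <- .counts_to_matrix(genes_b)
  na <- nrow(ma); nb <- nrow(mb)
  if (na + nb < 2L) stop("need at least two genes in total")
  pool <- rbind(ma, mb)
  old <- .save_rng(); on.exit(.restore_rng(old))
  reps <- vapply(seq_len(n_reps), function(i) {
    set.seed(.substream_seed(seed, 1000000L + i))
    idx <- sample.int(na + nb)
    pa <- .modal_profile_of(pool[idx[seq_len(na)], , drop = FALSE],
                            max_iter, tol)
    pb <- .modal_profile_of(pool[idx[(na + 1L):(na + nb)], , drop = FALSE],
                            max_iter, tol)
    .dist_num(pa, pb)
  }, numeric(1))
  list(null_mean = mean(reps), null_sd = stats::sd(reps), reps = reps)
}

#' Compare two replicate distance distributions
#'
#' Compares two vectors of replicate distances (e.g. the bootstrap
#' distribution of d(A,B) against that of d(C,D), or against a shuffled
#' null) by a z-test on the means when both look normal (Shapiro-Wilk on a
#' subsample of up to 500) or a two-sided Mann-Whitney test otherwise.
#'
#' @param reps_1,reps_2 numeric replicate vectors (length >= 30 for
#'   `method = "auto"`).
#' @param method `"auto"`, `"z"` or `"mann-whitney"`.
#' @return List: `p_value`, `method` actually used.
#' @export
distance_significance <- function(reps_1, reps_2,
                                  method = c("auto", "z", "mann-whitney")) {
  method <- match.arg(method)
  if (stats::sd(reps_1) == 0 && stats::sd(reps_2) == 0 &&
      mean(reps_1) == mean(reps_2))
    return(list(p_value = 1, method = "degenerate"))
  if (method == "auto") {
    if (length(reps_1) < 30L || length(reps_2) < 30L)
      stop("auto method needs >= 30 replicates per vector")
    sub <- function(x) if (length(x) > 500L) x[seq_len(500L)] else x
    normal <- tryCatch(
      stats::shapiro.test(sub(reps_1))$p.value > 0.05 &&
        stats::shapiro.test(sub(reps_2))$p.value > 0.05,
      error = function(e) FALSE)
    method <- if (normal) "z" else "mann-whitney"
  }
  if (method == "z") {
    se <- sqrt(stats::var(reps_1) / length(reps_1) +
                 stats::var(reps_2) / length(reps_2))
    if (se == 0) return(list(p_value = 1, method = "z"))
    z <- (mean(reps_1) - mean(reps_2)) / se
    list(p_value = 2 * stats::pnorm(-abs(z)), method = "z")
  } else {
    p <- stats::wilcox.test(reps_1, reps_2, exact = FALSE)$p.value
    list(p_value = p, method = "mann-whitney")
  }
}

#' Full distance report for a pair of gene sets
#'
#' Computes the point modal-usage distance between two gene sets, its
#' bootstrap mean and SD, the pooled-shuffle null mean and SD, a permutation
#' p-value of the point distance against the shuffled null (`p_perm`,
#' exact under exchangeability, floored at `1/(n_reps+1)`), and the z /
#' Mann-Whitney comparison of the bootstrap and null replicate vectors
#' (`p_value`) — the row structure of a gene-set distance table.
#'
#' @inheritParams bootstrap_distance
#' @param set_a,set_b labels for the two sets.
#' @param method significance method for the replicate-vector comparison.
#' @return A `distance_estimate` list with fields `set_a`, `set_b`, `point`,
#'   `boot_mean`, `boot_sd`, `null_mean`, `null_sd`, `n_reps`, `p_perm`,
#'   `p_value`, `test`, `seed`.
#' @export
distance_estimate <- function(genes_a, genes_b, set_a = "A", set_b = "B",
                              n_reps = 1000L, seed = 1L,
                              method = c("auto", "z", "mann-whitney"),
                              max_iter = 100L, tol = 1e-6) {
  ma <- .counts_to_matrix(genes_a); mb <- .counts_to_matrix(genes_b)
  point <- .dist_num(.modal_profile_of(ma, max_iter, tol),
                     .modal_profile_of(mb, max_iter, tol))
  bt <- bootstrap_distance(ma, mb, n_reps, seed, max_iter, tol)
  nl <- shuffled_null(ma, mb, n_reps, seed, max_iter, tol)
  sig <- distance_significance(bt$reps, nl$reps, method)
  p_perm <- (1 + sum(nl$reps >= point)) / (n_reps + 1)
  structure(list(set_a = set_a, set_b = set_b, point = point,
                 boot_mean = bt$boot_mean, boot_sd = bt$boot_sd,
                 null_mean = nl$null_mean, null_sd = nl$null_sd,
                 n_reps = n_reps, p_perm = p_perm,
                 p_value = sig$p_value, test = sig$method, seed = seed),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("%s vs %s: d = %.3f | boot %.3f +/- %.3f | null %.3f +/- %.3f | p_perm = %.4g (%s p = %.3g)\n",
              x$set_a, x$set_b, x$point, x$boot_mean, x$boot_sd,
              x$null_mean, x$null_sd, x$p_perm, x$test, x$p_value))
  invisible(x)
}
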