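# Neighbor-joining trees from usage-distance matrices and normalized
# Robinson-Foulds comparison of topologies.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric
#' zero-diagonal distance matrix. NJ can emit negative branch lengths on
#' non-additive data; these are clamped to zero with the deficit moved to
#' the adjacent branch (the edge below the same node), standard practice,
#' and the number of clamped edges is recorded in the `clamped` attribute.
#'
#' @param dist symmetric numeric matrix, zero diagonal, `n >= 3`.
#' @param labels optional leaf labels (default from `dimnames`).
#' @return An unrooted `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(dist, labels = NULL) {
  d <- as.matrix(dist)
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2L]
    below <- which(tr$edge[, 1L] == child)
    if (length(below)) tr$edge.length[below] <- tr$edge.length[below] + deficit
  }
  attr(tr, "clamped") <- length(neg)
  tr
}

#' Normalized Robinson-Foulds distance
#'
#' The Robinson-Foulds bipartition count between two unrooted trees on the
#' same leaves, divided by its maximum `2 * (n - 3)` for binary trees, so 0
#' means identical topologies and 1 means no shared nontrivial splits;
#' `1 - value` is the fraction of branch coincidence.
#'
#' @param t1,t2 `phylo` trees with identical leaf label sets.
#' @return Normalized RF distance in `[0, 1]`.
#' @export
normalized_rf <- function(t1, t2) {
  if (!inherits(t1, "phylo") || !inherits(t2, "phylo"))
    stop("inputs must be phylo trees")
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  as.numeric(phangorn::RF.dist(t1, t2, normalize = TRUE, check.labels = TRUE))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric matrix with dimnames.
#' @param path output file.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(substr(rownames(d)[i], 1, 10), width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file written by [write_phylip_dist()] or PHYLIP tools.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  labs <- character(n); d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    labs[i] <- parts[1L]
    d[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(d) <- list(labs, labs)
  d
}
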