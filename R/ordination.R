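# Correspondence analysis of per-gene RSCU matrices, with supplementary-row
# projection of modal profiles (the transition-formula equivalent of adding
# an artificial modal sequence as an extra observation).

#' Correspondence analysis
#'
#' Standard CA by SVD of the matrix of standardised residuals:
#' `P = X / sum(X)`; `S = D_r^{-1/2} (P - r c') D_c^{-1/2}`; the SVD of `S`
#' gives principal coordinates `D_r^{-1/2} U diag(d)` for rows (analogously
#' for columns) and total inertia `sum(d^2)` — the chi-square statistic of
#' the table divided by its grand total. All-zero rows and columns are
#' dropped (recorded in attributes).
#'
#' @param x non-negative matrix (e.g. genes x 59 RSCU from [rscu_matrix()]);
#'   at least 3 rows.
#' @return A `ca_model` list: `sv` (singular values, descending),
#'   `row_coords`, `col_coords` (principal coordinates), `col_standard`
#'   (standard column coordinates used for supplementary projection),
#'   `row_masses`, `col_masses`, `total_inertia`, `dropped_rows`,
#'   `dropped_cols`.
#' @export
correspondence_analysis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || anyNA(x)) stop("CA input must be non-negative, no NA")
  dr <- which(rowSums(x) == 0); dc <- which(colSums(x) == 0)
  if (length(dr)) x <- x[-dr, , drop = FALSE]
  if (length(dc)) x <- x[, -dc, drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 non-empty rows")
  P <- x / sum(x)
  r <- rowSums(P); cc <- colSums(P)
  S <- sweep(sweep(P - tcrossprod(r, cc), 1L, sqrt(r), "/"),
             2L, sqrt(cc), "/")
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  if (length(keep) == 0L) {
    k <- min(dim(x)) - 1L
    zero <- matrix(0, nrow(x), max(k, 1L),
                   dimnames = list(rownames(x), NULL))
    return(structure(list(sv = numeric(0), row_coords = zero,
                          col_coords = matrix(0, ncol(x), max(k, 1L),
                                              dimnames = list(colnames(x), NULL)),
                          col_standard = matrix(0, ncol(x), max(k, 1L),
                                                dimnames = list(colnames(x), NULL)),
                          row_masses = r, col_masses = cc,
                          total_inertia = 0,
                          dropped_rows = dr, dropped_cols = dc),
                     class = "ca_model"))
  }
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]
  row_coords <- sweep(U %*% diag(d, length(d)), 1L, sqrt(r), "/")
  col_coords <- sweep(V %*% diag(d, length(d)), 1L, sqrt(cc), "/")
  col_standard <- sweep(V, 1L, sqrt(cc), "/")
  dimnames(row_coords) <- list(rownames(x), paste0("C", seq_along(d)))
  dimnames(col_coords) <- list(colnames(x), paste0("C", seq_along(d)))
  dimnames(col_standard) <- dimnames(col_coords)
  structure(list(sv = d, row_coords = row_coords, col_coords = col_coords,
                 col_standard = col_standard, row_masses = r,
                 col_masses = cc, total_inertia = sum(d^2),
                 dropped_rows = dr, dropped_cols = dc),
            class = "ca_model")
}

#' @export
print.ca_model <- function(x, ...) {
  cat("CA:", nrow(x$row_coords), "rows x", nrow(x$col_coords), "cols;",
      length(x$sv), "components; total inertia", signif(x$total_inertia, 4),
      "\n")
  invisible(x)
}

#' Project a supplementary row into a CA space
#'
#' Applies the supplementary-row transition formula: the vector is
#' normalised to a profile and multiplied by the standard column
#' coordinates. Projecting an active row's profile reproduces that row's
#' principal coordinates; the column-mass centroid projects to the origin.
#' The model is not altered.
#'
#' @param model a `ca_model`.
#' @param v non-negative vector over the model's retained columns (e.g. a
#'   modal profile's RSCU).
#' @return Numeric coordinate vector over the model's components.
#' @export
project_supplementary <- function(model, v) {
  cols <- rownames(model$col_standard)
  if (!is.null(names(v)) && !is.null(cols)) v <- v[cols]
  v <- as.numeric(v)
  if (length(v) != nrow(model$col_standard))
    stop("vector length does not match the model's retained columns")
  if (anyNA(v)) stop("supplementary vector has NA over retained columns")
  if (sum(v) == 0) stop("cannot project a zero vector")
  as.numeric((v / sum(v)) %*% model$col_standard)
}
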