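# Readers and writers for the plain-text formats the pipeline consumes:
# CDS FASTA, gene-set maps, tRNA copy-number and wobble-rule tables,
# ortholog / contig / COG / abundance TSVs, and result tables.

#' Read a CDS collection from FASTA
#'
#' @param path FASTA file, one record per gene.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a two-column gene-set map
#'
#' @param path TSV with columns `gene_id`, `set` (header optional if those
#'   names are present).
#' @return Data frame `gene_id`, `set`.
#' @export
read_set_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "set") %in% names(df)))
    names(df)[1:2] <- c("gene_id", "set")
  df[c("gene_id", "set")]
}

#' Read a tRNA gene copy-number table
#'
#' @param path TSV with columns `anticodon` (5'-3', DNA alphabet) and
#'   `tGCN`.
#' @return Named integer vector anticodon -> copy number.
#' @export
read_trna_pool <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("anticodon", "tGCN") %in% names(df)))
  ac <- toupper(df$anticodon)
  if (any(!grepl("^[ACGT]{3}$", ac)))
    stop("invalid anticodon(s) in ", path)
  if (any(df$tGCN < 0)) stop("negative tRNA gene copy number")
  stats::setNames(as.integer(df$tGCN), ac)
}

#' Read a codon-anticodon pairing efficiency table
#'
#' @param path TSV with columns `codon`, `anticodon`, `s` (the fitted
#'   selective constraint of the pairing, in `[0, 1]`).
#' @return Rules data frame usable by [absolute_adaptiveness()].
#' @export
read_wobble_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "anticodon", "s") %in% names(df)))
  df$codon <- toupper(df$codon); df$anticodon <- toupper(df$anticodon)
  .check_rules(df[c("codon", "anticodon", "s")])
}

#' Read an ortholog presence/absence table
#'
#' @param path TSV with `gene_id`, optional `replicon`, and 0/1 strain
#'   columns.
#' @return Data frame.
#' @export
read_ortholog_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a contig metadata table
#'
#' @param path TSV with `contig_id`, `length`, `coverage`,
#'   `max_identity_pct`.
#' @return Data frame.
#' @export
read_contig_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length", "coverage", "max_identity_pct")
                %in% names(df)))
  df
}

#' Read a COG assignment table
#'
#' @param path TSV with `gene_id`, `cog_class`.
#' @return Named character vector gene_id -> class.
#' @export
read_cog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "cog_class") %in% names(df)))
  stats::setNames(df$cog_class, df$gene_id)
}

#' Read a protein abundance table
#'
#' @param path TSV with `gene_id`, `abundance`.
#' @return Named numeric vector gene_id -> abundance.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "abundance") %in% names(df)))
  stats::setNames(as.numeric(df$abundance), df$gene_id)
}

#' Write a per-gene codon-count matrix as TSV
#'
#' @param counts_matrix genes x 61 matrix.
#' @param path output TSV (gene_id + 61 codon columns).
#' @export
write_counts_tsv <- function(counts_matrix, path) {
  df <- data.frame(gene_id = rownames(counts_matrix), counts_matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write usage profiles as a TSV (one row per set)
#'
#' @param profiles named list of `usage_profile`s.
#' @param path output TSV (set + 59 codon columns).
#' @export
write_profiles_tsv <- function(profiles, path) {
  m <- do.call(rbind, lapply(profiles, as.numeric))
  colnames(m) <- syn_codons()
  df <- data.frame(set = names(profiles), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collect distance estimates into a table
#'
#' @param estimates list of `distance_estimate` objects.
#' @return Data frame with the point, bootstrap, null, and p-value columns.
#' @export
distance_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(set_a = e$set_a, set_b = e$set_b, point = e$point,
               boot_mean = e$boot_mean, boot_sd = e$boot_sd,
               null_mean = e$null_mean, null_sd = e$null_sd,
               n_reps = e$n_reps, p_perm = e$p_perm,
               p_value = e$p_value, test = e$test,
               stringsAsFactors = FALSE)))
}
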