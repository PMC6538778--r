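#' @keywords internal
"_PACKAGE"

# Genetic-code bookkeeping. Everything downstream indexes codons by the fixed
# alphabetical orderings built here at load time from the standard (table 11 /
# table 1 identical for bacteria) genetic code shipped with Biostrings.

.code_env <- new.env(parent = emptyenv())

.build_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  aa <- gc[codons]
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  sense_aa <- aa[sense]
  fam_sizes <- table(sense_aa)
  syn <- sense[fam_sizes[sense_aa] >= 2L] # drops ATG (Met), TGG (Trp)
  syn_aa <- sense_aa[syn]

  # indicator matrix: SYN59 codon -> amino-acid family (18 families)
  fams <- sort(unique(syn_aa))
  fam_ind <- matrix(0L, length(syn), length(fams),
                    dimnames = list(syn, fams))
  fam_ind[cbind(seq_along(syn), match(syn_aa, fams))] <- 1L

  list(
    map = gc,
    stop3 = stops,
    sense61 = sense,
    sense_aa = sense_aa,
    syn59 = syn,
    syn_aa = syn_aa,
    families = fams,
    fam_sizes = as.integer(fam_sizes[fams]),
    fam_ind = fam_ind,
    third_gc_sense = substr(sense, 3L, 3L) %in% c("G", "C"),
    third_gc_syn = substr(syn, 3L, 3L) %in% c("G", "C")
  )
}

.code <- function() {
  if (is.null(.code_env$code)) .code_env$code <- .build_code()
  .code_env$code
}

#' Sense codons of the standard genetic code
#'
#' The 61 sense codons (alphabetical, DNA alphabet) of the standard bacterial
#' genetic code. All codon-count vectors and matrices in the package are
#' indexed by this ordering.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .code()$sense61

#' Synonymously degenerate codons
#'
#' The 59 sense codons belonging to amino acids with two or more synonymous
#' codons, i.e. the sense codons excluding ATG (Met) and TGG (Trp). RSCU
#' vectors and usage profiles are indexed by this ordering.
#'
#' @return Character vector of length 59.
#' @export
syn_codons <- function() .code()$syn59

#' Stop codons
#' @return Character vector: TAA, TAG, TGA.
#' @export
stop_codons <- function() .code()$stop3

#' Amino acid of each codon
#'
#' @param codons character vector of codons (DNA alphabet).
#' @return One-letter amino-acid codes; `"*"` for stop codons.
#' @export
codon_aa <- function(codons) {
  unname(.code()$map[toupper(codons)])
}

#' Synonymous-family structure of the degenerate codons
#'
#' @return A list with `families` (18 one-letter amino-acid codes),
#'   `sizes` (number of synonymous codons per family) and `membership`
#'   (a 59 x 18 0/1 indicator matrix mapping codons to families).
#' @export
codon_families <- function() {
  cd <- .code()
  list(families = cd$families, sizes = cd$fam_sizes, membership = cd$fam_ind)
}
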