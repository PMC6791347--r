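# Codon bookkeeping shared by the simulator and the selection engine.
# Everything is expressed over the 61 sense codons of the standard code,
# ordered alphabetically (AAA, AAC, ..., TTT minus TAA/TAG/TGA).

.nucs <- c("A", "C", "G", "T")

.all_codons <- as.vector(outer(outer(.nucs, .nucs, paste0), .nucs, paste0))
.all_codons <- sort(.all_codons)

.stop_codons <- c("TAA", "TAG", "TGA")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in alphabetical order,
#'   the state order used by all codon-model matrices in this package.
#' @export
sense_codons <- function() setdiff(.all_codons, .stop_codons)

.codons <- setdiff(.all_codons, .stop_codons)

# codon -> one-letter amino acid, stops are "*"
.codon_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc[.all_codons]), .all_codons)
})

#' Translate a codon string vector
#'
#' Codons containing anything outside ACGT (gaps, N, ?) translate to "X";
#' stop codons translate to "*".
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector of one-letter amino acids.
#' @export
translate_codons <- function(codons) {
  aa <- .codon_aa[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Pairwise classification of the 61x61 codon grid, computed once at load:
# 0 = not a single-nucleotide change, 1 = synonymous transversion,
# 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition.
.codon_pair_class <- local({
  n <- length(.codons)
  m1 <- substring(.codons, 1L, 1L)
  m2 <- substring(.codons, 2L, 2L)
  m3 <- substring(.codons, 3L, 3L)
  cls <- matrix(0L, n, n, dimnames = list(.codons, .codons))
  d1 <- outer(m1, m1, "!=")
  d2 <- outer(m2, m2, "!=")
  d3 <- outer(m3, m3, "!=")
  ndiff <- d1 + d2 + d3
  one <- ndiff == 1L
  ts <- (d1 & outer(m1, m1, .is_transition)) |
    (d2 & outer(m2, m2, .is_transition)) |
    (d3 & outer(m3, m3, .is_transition))
  aa <- .codon_aa[.codons]
  syn <- outer(aa, aa, "==")
  cls[one & syn & !ts] <- 1L
  cls[one & syn & ts] <- 2L
  cls[one & !syn & !ts] <- 3L
  cls[one & !syn & ts] <- 4L
  cls
})

#' Map codon strings to sense-codon state indices
#'
#' @param codons character vector of 3-letter codon strings.
#' @return integer vector of indices into [sense_codons()]; any codon that
#'   is not one of the 61 sense codons (gap columns, codons containing N or
#'   ?, stop codons) maps to `NA`, the fully-ambiguous state.
#' @export
codon_index <- function(codons) {
  match(codons, .codons)
}
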