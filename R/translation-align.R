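# Codon-aware translation alignment: sequences are translated, proteins are
# aligned progressively under BLOSUM62 (guide tree from p-distances), and
# the protein alignment is back-threaded to codons. Premature and terminal
# stop codons enter the codon alignment as the fully-ambiguous state "???";
# frameshift indels must already have been removed from the inputs (see
# frame_corrected_cds()), so every input is a frame-consistent triplet
# string.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.blosum62_sub <- local({
  b62 <- NULL
  function() {
    if (is.null(b62)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b62 <<- e$BLOSUM62[.aa_alphabet, .aa_alphabet]
    }
    b62
  }
})

# protein profile: L x 21 residue-frequency matrix (rows sum to the
# non-gap fraction of the column)
.profile <- function(aligned_aas) {
  L <- nchar(aligned_aas[[1L]])
  m <- matrix(0, L, length(.aa_alphabet),
              dimnames = list(NULL, .aa_alphabet))
  for (s in aligned_aas) {
    ch <- strsplit(s, "")[[1L]]
    keep <- ch != "-"
    ch[!ch %in% .aa_alphabet & keep] <- "X"
    idx <- cbind(which(keep), match(ch[keep], .aa_alphabet))
    m[idx] <- m[idx] + 1
  }
  m / length(aligned_aas)
}

.merge_alignments <- function(A, B, gap_open = 10, gap_ext = 0.5) {
  b62 <- .blosum62_sub()
  pa <- .profile(A)
  pb <- .profile(B)
  S <- pa %*% b62 %*% t(pb)
  al <- profile_align(S, gap_open, gap_ext)
  thread <- function(seqs, idx) {
    vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1L]]
      out <- rep("-", length(idx))
      out[idx > 0L] <- ch[idx[idx > 0L]]
      paste(out, collapse = "")
    }, character(1))
  }
  c(thread(A, al$i), thread(B, al$j))
}

#' Codon-aware translation alignment
#'
#' @param cds_set named character vector (or list) of frame-consistent
#'   nucleotide strings: length divisible by 3, with `N` / `?` allowed.
#'   Frameshift indels must have been removed beforehand; a sequence whose
#'   length is not a multiple of 3 is an error naming the taxon.
#' @param gap_open,gap_ext affine gap penalties on the BLOSUM62 scale.
#' @return a [codon_alignment()]; gap columns are `"---"`, stop codons
#'   (premature or terminal) become `"???"`.
#' @export
translation_align <- function(cds_set, gap_open = 10, gap_ext = 0.5) {
  cds_set <- vapply(cds_set, toupper, character(1))
  if (is.null(names(cds_set)) || any(names(cds_set) == ""))
    stop("cds_set must be named by taxon")
  bad <- names(cds_set)[nchar(cds_set) %% 3L != 0L]
  if (length(bad) > 0L)
    stop("sequence not reducible to a frame-consistent triplet string: ",
         paste(bad, collapse = ", "))
  n <- length(cds_set)
  codons <- lapply(cds_set, .split_codons)
  prots <- vapply(codons, function(cd) {
    aa <- translate_codons(cd)
    aa[aa == "*"] <- "X"   # stops align as unknown residues
    paste(aa, collapse = "")
  }, character(1))

  if (n == 1L) {
    aligned <- prots
  } else {
    # guide order from protein p-distances (average-linkage clustering)
    d <- matrix(0, n, n)
    if (n > 2L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        pi_ <- strsplit(prots[i], "")[[1L]]
        pj <- strsplit(prots[j], "")[[1L]]
        L <- min(length(pi_), length(pj))
        ok <- pi_[1:L] != "X" & pj[1:L] != "X"
        d[i, j] <- d[j, i] <-
          if (any(ok)) mean(pi_[1:L][ok] != pj[1:L][ok]) else 1
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    merged_sets <- vector("list", n - 1L)
    pick <- function(k) if (k < 0L) prots[-k] else merged_sets[[k]]
    for (step in seq_len(n - 1L)) {
      A <- pick(hc$merge[step, 1L])
      B <- pick(hc$merge[step, 2L])
      merged_sets[[step]] <-
        if (nchar(A[[1L]]) == 0L) B
        else if (nchar(B[[1L]]) == 0L) A
        else .merge_alignments(A, B, gap_open, gap_ext)
    }
    aligned <- merged_sets[[n - 1L]]
  }

  # back-thread to codons
  L <- nchar(aligned[[1L]])
  taxa <- names(cds_set)
  cm <- matrix("---", length(taxa), L, dimnames = list(taxa, NULL))
  for (t in taxa) {
    ch <- strsplit(aligned[[t]], "")[[1L]]
    cd <- codons[[t]]
    k <- 0L
    for (col in seq_len(L)) {
      if (ch[col] == "-") next
      k <- k + 1L
      codon <- cd[k]
      if (codon %in% .stop_codons || grepl("\\?", codon))
        codon <- "???"
      cm[t, col] <- codon
    }
  }
  codon_alignment(cm)
}
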