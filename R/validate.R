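# Read-based validation of called mutations. Instead of a full mapping +
# pileup, each read is scored against two haplotype windows (mutant as
# observed in the region, wild type with the reference allele restored);
# reads that span the site with enough anchor on both sides and score
# strictly better on one haplotype vote for it. This is exact for the
# short indels and nonsense changes in scope.

.read_submat <- local({
  m <- matrix(-3, 5, 5, dimnames = list(c(.nucs, "N"), c(.nucs, "N")))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
})

# local-align a set of reads to a window; returns score and subject range
.align_reads <- function(reads, window) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads), subject = window,
    type = "local", substitutionMatrix = .read_submat,
    gapOpening = 5, gapExtension = 2)
  data.frame(score = Biostrings::score(aln),
             sstart = Biostrings::start(Biostrings::subject(aln)),
             send = Biostrings::end(Biostrings::subject(aln)))
}

.best_strand <- function(reads, window) {
  f <- .align_reads(reads, window)
  r <- .align_reads(revcomp(reads), window)
  use_r <- r$score > f$score
  f[use_r, ] <- r[use_r, ]
  f
}

# Cheap k-mer prescreen: keep reads sharing an exact k-mer (either
# orientation) with any haplotype window. Reads from elsewhere in the
# locus cannot be informative and dominate the input; aligning them all is
# wasted work. With tiled k-mers (step k/3) a read overlapping a window by
# >= 2k/3 passes unless sequencing errors hit every tile.
.prefilter_reads <- function(reads, windows, k = 18L) {
  tiles <- unique(unlist(lapply(windows, function(w) {
    if (nchar(w) < k) return(w)
    s <- unique(c(seq(1L, nchar(w) - k + 1L, by = max(1L, k %/% 3L)),
                  nchar(w) - k + 1L))
    substring(w, s, s + k - 1L)
  })))
  tiles <- unique(c(tiles, revcomp(tiles)))
  subj <- Biostrings::DNAStringSet(reads)
  keep <- rep(FALSE, length(reads))
  for (tl in tiles) {
    if (all(keep)) break
    keep <- keep | Biostrings::vcountPattern(tl, subj, fixed = TRUE) > 0L
  }
  reads[keep]
}

#' Validate one mutation against sequencing reads
#'
#' Builds the mutant haplotype window (the region as observed, mutation
#' +/- `flank_nt`) and the wild-type window (reference allele restored),
#' aligns every read (both orientations) to both, and counts reads that
#' span the variant with at least `flank_nt / 2` anchored on each side and
#' score strictly better on one haplotype.
#'
#' @param mutation one row of a [call_inactivating_mutations()] table (needs
#'   `region_coord`, `ref_allele`, `alt_allele`).
#' @param region the region the mutation was called on: a `GenomicLocus`,
#'   a [map_reference_cds()] result (its aligned-strand sequence is used),
#'   or a nucleotide string.
#' @param reads named character vector of read sequences.
#' @param flank_nt haplotype window flank (>= 10, default 50).
#' @param min_reads minimum informative reads for a verdict (default 3).
#' @param conf_thr confirmation threshold on the support fraction (default
#'   0.8; the refutation threshold is `1 - conf_thr`, and the band between
#'   is called polymorphic).
#' @return a `ValidationVerdict`: list with `n_support`, `n_contradict`,
#'   `support_fraction`, `verdict` in confirmed / refuted / polymorphic /
#'   no_data.
#' @export
validate_mutation <- function(mutation, region, reads, flank_nt = 50L,
                              min_reads = 3L, conf_thr = 0.8) {
  stopifnot(flank_nt >= 10L, conf_thr > 0.5, conf_thr <= 1)
  seq <- if (inherits(region, "GenomicLocus")) region$seq
    else if (inherits(region, "MappedAlignment")) region$region_seq
    else region
  seq <- toupper(seq)
  site <- mutation$region_coord
  alt <- toupper(mutation$alt_allele)
  ref <- toupper(mutation$ref_allele)
  if (is.na(site) || site < 1L || site + nchar(alt) - 1L > nchar(seq))
    stop("mutation coordinate outside region")
  if (substr(seq, site, site + nchar(alt) - 1L) != alt)
    stop("region does not carry the recorded alt allele at region_coord")

  a <- max(1L, site - flank_nt)
  b <- min(nchar(seq), site + nchar(alt) - 1L + flank_nt)
  mut_win <- substr(seq, a, b)
  wt_win <- paste0(substr(seq, a, site - 1L), ref,
                   substring(substr(seq, a, b), site - a + nchar(alt) + 1L))
  # variant interval inside each window, expanded by the anchor requirement
  anchor <- flank_nt / 2
  mut_iv <- c(site - a + 1L - anchor, site - a + nchar(alt) + anchor)
  wt_iv <- c(site - a + 1L - anchor, site - a + nchar(ref) + anchor)

  if (length(reads) > 50L)
    reads <- .prefilter_reads(reads, c(mut_win, wt_win))
  if (length(reads) == 0L)
    return(structure(list(n_support = 0L, n_contradict = 0L,
                          support_fraction = NA_real_, verdict = "no_data"),
                     class = "ValidationVerdict"))

  sm <- .best_strand(reads, mut_win)
  sw <- .best_strand(reads, wt_win)
  spans_mut <- sm$sstart <= mut_iv[1] & sm$send >= mut_iv[2]
  spans_wt <- sw$sstart <= wt_iv[1] & sw$send >= wt_iv[2]
  support <- sm$score > sw$score & spans_mut
  contra <- sw$score > sm$score & spans_wt
  n_s <- sum(support)
  n_c <- sum(contra)
  n_inf <- n_s + n_c
  if (n_inf < min_reads) {
    verdict <- "no_data"
    frac <- if (n_inf > 0) n_s / n_inf else NA_real_
  } else {
    frac <- n_s / n_inf
    verdict <- if (frac >= conf_thr) "confirmed"
      else if (frac <= 1 - conf_thr) "refuted"
      else "polymorphic"
  }
  structure(list(n_support = n_s, n_contradict = n_c,
                 support_fraction = frac, verdict = verdict),
            class = "ValidationVerdict")
}

#' @export
print.ValidationVerdict <- function(x, ...) {
  cat(sprintf("ValidationVerdict: %s (%d support / %d contradict%s)\n",
              x$verdict, x$n_support, x$n_contradict,
              if (!is.na(x$support_fraction))
                sprintf(", support fraction %.2f", x$support_fraction)
              else ""))
  invisible(x)
}

#' Validate all mutations against one or more read sets
#'
#' Per read set each mutation gets a [validate_mutation()] verdict; the
#' consensus is `confirmed` only if no set refutes and at least one
#' confirms, `refuted` symmetrically, `no_data` when no set is informative,
#' and `polymorphic_or_conflict` when sets disagree or any set reports a
#' polymorphic split.
#'
#' @param mutations a [call_inactivating_mutations()] table.
#' @param region see [validate_mutation()].
#' @param read_sets named list of read vectors (independent sequencing
#'   projects).
#' @param ... passed to [validate_mutation()].
#' @return data frame: one row per mutation x read set plus a `consensus`
#'   column repeated per mutation.
#' @export
validate_all <- function(mutations, region, read_sets, ...) {
  stopifnot(length(read_sets) >= 1L, !is.null(names(read_sets)))
  out <- list()
  for (i in seq_len(nrow(mutations))) {
    vs <- lapply(read_sets, function(rs)
      validate_mutation(mutations[i, ], region, rs, ...))
    verdicts <- vapply(vs, `[[`, character(1), "verdict")
    fracs <- vapply(vs, `[[`, numeric(1), "support_fraction")
    informative <- verdicts[verdicts != "no_data"]
    consensus <- if (length(informative) == 0L) "no_data"
      else if (any(informative == "polymorphic")) "polymorphic_or_conflict"
      else if (any(informative == "confirmed") &&
               any(informative == "refuted")) "polymorphic_or_conflict"
      else if (any(informative == "confirmed")) "confirmed"
      else "refuted"
    out[[i]] <- data.frame(
      mutation = i, kind = mutations$kind[i],
      ref_coord = mutations$ref_coord[i],
      read_set = names(read_sets), verdict = verdicts,
      support_fraction = fracs, consensus = consensus,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
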