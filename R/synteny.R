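# Locus orthology by synteny: local alignment of neighbor genes against
# target contigs (megablast-like scoring), ranked best hits, an ordered
# synteny map, and extraction of the candidate region between anchor
# genes. Coordinates are 0-based half-open internally and 1-based
# inclusive in reports.

.synteny_submat <- local({
  m <- matrix(-3, 5, 5, dimnames = list(c(.nucs, "N"), c(.nucs, "N")))
  diag(m) <- 2
  m["N", ] <- 0
  m[, "N"] <- 0
  m
})

.hit_row <- function(query_gene, contig, start0, end0, strand, identity,
                     coverage, aln_len, score) {
  data.frame(query_gene = query_gene, target_contig = contig,
             start = start0, end = end0, strand = strand,
             percent_identity = identity, query_coverage = coverage,
             aln_len = aln_len, score = score, stringsAsFactors = FALSE)
}

#' Best local-alignment hit of a gene against a contig set
#'
#' Affine-gap Smith-Waterman (match 2 / mismatch -3 / gap open 5 / gap
#' extend 2, megablast-like) against both strands of every contig.
#' Candidates are ranked lexicographically by (query coverage, percent
#' identity), ties broken by alignment length, contig name, then smaller
#' start, making the choice a total order independent of input order.
#'
#' @param query_gene_seq nucleotide string.
#' @param target_contigs named character vector of contig sequences.
#' @param min_identity,min_coverage acceptance thresholds in percent
#'   (defaults 70 / 50).
#' @param query_name label recorded in the hit.
#' @return a one-row `GeneHit` data frame (0-based half-open coordinates),
#'   or `NULL` when no hit passes the thresholds.
#' @export
best_hit <- function(query_gene_seq, target_contigs, min_identity = 70,
                     min_coverage = 50, query_name = "query") {
  if (length(target_contigs) == 0L) stop("empty contig set")
  if (is.null(names(target_contigs)))
    names(target_contigs) <- paste0("contig", seq_along(target_contigs))
  query_gene_seq <- toupper(query_gene_seq)
  stopifnot(nchar(query_gene_seq) > 0L)
  qlen <- nchar(query_gene_seq)

  cand <- list()
  for (cn in names(target_contigs)) {
    subj <- toupper(target_contigs[[cn]])
    clen <- nchar(subj)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subj else revcomp(subj)
      aln <- Biostrings::pairwiseAlignment(
        pattern = query_gene_seq, subject = s, type = "local",
        substitutionMatrix = .synteny_submat,
        gapOpening = 5, gapExtension = 2)
      if (Biostrings::score(aln) <= 0) next
      pa <- as.character(Biostrings::alignedPattern(aln))
      sa <- as.character(Biostrings::alignedSubject(aln))
      pc <- strsplit(pa, "")[[1L]]
      sc <- strsplit(sa, "")[[1L]]
      aln_len <- length(pc)
      ident <- 100 * sum(pc == sc & pc %in% .nucs) / aln_len
      cov <- 100 * sum(pc != "-") / qlen
      st <- Biostrings::start(Biostrings::subject(aln))
      en <- Biostrings::end(Biostrings::subject(aln))
      if (strand == "-") {
        tmp <- clen - en + 1L
        en <- clen - st + 1L
        st <- tmp
      }
      cand[[length(cand) + 1L]] <-
        .hit_row(query_name, cn, st - 1L, en, strand, ident, cov, aln_len,
                 Biostrings::score(aln))
    }
  }
  if (length(cand) == 0L) return(NULL)
  hits <- do.call(rbind, cand)
  hits <- hits[hits$percent_identity >= min_identity &
                 hits$query_coverage >= min_coverage, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$query_coverage, -hits$percent_identity,
               -hits$aln_len, hits$target_contig, hits$start)
  out <- hits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a synteny map of neighbor genes against a target genome
#'
#' One [best_hit()] per neighbor, sorted per contig by target coordinate;
#' neighbors without an accepted hit are recorded as absent. When the
#' focal-gene sequence is supplied its presence is flagged too.
#'
#' @param reference_neighbors named character vector of neighbor gene
#'   sequences, ordered by reference coordinate.
#' @param target_genome named character vector of contigs.
#' @param focal_gene optional focal-gene sequence.
#' @param ... thresholds passed to [best_hit()].
#' @return a `SyntenyMap`: list with `hits` (one row per neighbor, absent
#'   ones with NA coordinates, sorted by contig then start),
#'   `focal_present`, `focal_hit`.
#' @export
build_synteny_map <- function(reference_neighbors, target_genome,
                              focal_gene = NULL, ...) {
  stopifnot(!is.null(names(reference_neighbors)))
  rows <- lapply(names(reference_neighbors), function(g) {
    h <- best_hit(reference_neighbors[[g]], target_genome,
                  query_name = g, ...)
    if (is.null(h))
      h <- .hit_row(g, NA_character_, NA_integer_, NA_integer_,
                    NA_character_, NA_real_, NA_real_, NA_integer_, NA_real_)
    h
  })
  hits <- do.call(rbind, rows)
  present <- !is.na(hits$target_contig)
  hits <- rbind(hits[present, , drop = FALSE][
    order(hits$target_contig[present], hits$start[present]), ,
    drop = FALSE],
    hits[!present, , drop = FALSE])
  rownames(hits) <- NULL
  focal_hit <- if (!is.null(focal_gene))
    best_hit(focal_gene, target_genome, query_name = "focal", ...)
  structure(list(hits = hits,
                 focal_present = !is.null(focal_gene) &&
                   !is.null(focal_hit),
                 focal_hit = focal_hit),
            class = "SyntenyMap")
}

#' @export
print.SyntenyMap <- function(x, ...) {
  cat("SyntenyMap:", sum(!is.na(x$hits$target_contig)), "of",
      nrow(x$hits), "neighbors placed; focal gene",
      if (isTRUE(x$focal_present)) "present" else "absent/not searched",
      "\n")
  print(x$hits[, c("query_gene", "target_contig", "start", "end",
                   "strand", "percent_identity", "query_coverage")])
  invisible(x)
}

#' Extract the candidate region between two anchor hits
#'
#' Returns the inter-anchor interval expanded by `padding_nt` and clipped
#' to the contig, as a `GenomicLocus`; the strand is inferred from the
#' anchor orientations. Anchors on different contigs raise an error of
#' class `synteny_unresolved` (callers should fall back to a direct CDS
#' search); anchors on opposite strands produce a warning but still an
#' interval.
#'
#' @param upstream_anchor_hit,downstream_anchor_hit `GeneHit` rows.
#' @param contigs named character vector containing the hit contig.
#' @param padding_nt expansion on each side (default 1000).
#' @return a `GenomicLocus` with `interval` (1-based inclusive on the
#'   contig).
#' @export
locate_target_region <- function(upstream_anchor_hit, downstream_anchor_hit,
                                 contigs, padding_nt = 1000L) {
  u <- upstream_anchor_hit
  d <- downstream_anchor_hit
  if (is.null(u) || is.null(d) || is.na(u$target_contig) ||
      is.na(d$target_contig) || u$target_contig != d$target_contig)
    stop(structure(class = c("synteny_unresolved", "error", "condition"),
                   list(message = paste(
                     "region not resolvable: anchors on different contigs;",
                     "fall back to direct CDS search"),
                     call = sys.call(-1))))
  if (!is.na(u$strand) && !is.na(d$strand) && u$strand != d$strand)
    warning("anchor hits on opposite strands; interval still returned")
  contig <- toupper(contigs[[u$target_contig]])
  clen <- nchar(contig)
  lo <- min(u$end, d$end)        # 0-based half-open ends
  hi <- max(u$start, d$start)    # 0-based starts
  start0 <- max(0L, lo - padding_nt)
  end0 <- min(clen, hi + padding_nt)
  if (end0 <= start0)
    stop("empty inter-anchor interval")
  strand <- if (!is.na(u$strand) && u$strand == "-" &&
                !is.na(d$strand) && d$strand == "-") "-" else "+"
  structure(list(name = paste0(u$target_contig, ":", start0 + 1L, "-",
                               end0),
                 seq = substr(contig, start0 + 1L, end0),
                 strand = strand,
                 interval = c(start0 + 1L, end0),
                 contig = u$target_contig,
                 cds_interval = c(NA_integer_, NA_integer_),
                 n_runs = data.frame(start = integer(0), end = integer(0))),
            class = "GenomicLocus")
}

#' Write a synteny map as TSV (1-based inclusive coordinates)
#'
#' @param map a `SyntenyMap`.
#' @param path output file.
#' @export
write_synteny_tsv <- function(map, path) {
  h <- map$hits
  h$start <- h$start + 1L   # report 1-based inclusive
  write_tsv(h[, c("query_gene", "target_contig", "start", "end", "strand",
                  "percent_identity", "query_coverage")], path)
}
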