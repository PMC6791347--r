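# Reference-guided CDS reconstruction and ORF-abolishing mutation calling.
# A single-exon reference gene (UTR-flanked) is mapped onto a genomic
# region by semi-global affine alignment (reference global, region local),
# the alignment is screened for frameshift indels and in-frame premature
# stop codons, sliding-window identity flags truncations, and a coding
# status (intact / eroded / inconclusive) is assigned per taxon.

#' Reference gene for annotation
#'
#' @param cds coding sequence: length divisible by 3, terminal stop codon,
#'   no internal stops.
#' @param utr5,utr3 flanking untranslated sequence (may be empty).
#' @param name gene name.
#' @param taxon source taxon.
#' @return a `ReferenceGene`.
#' @export
reference_gene <- function(cds, utr5 = "", utr3 = "", name = "gene",
                           taxon = "reference") {
  cds <- toupper(cds)
  cods <- .split_codons(cds)
  if (!cods[length(cods)] %in% .stop_codons)
    stop("reference CDS must end in a stop codon")
  if (any(cods[-length(cods)] %in% .stop_codons))
    stop("reference CDS contains an internal stop codon")
  structure(list(cds = cds, utr5 = toupper(utr5), utr3 = toupper(utr3),
                 name = name, taxon = taxon),
            class = "ReferenceGene")
}

# Scoring matrix for reference mapping: match 1 / mismatch -2, N matches
# anything at zero score (assembly gaps are uninformative, not mismatches).
.map_submat <- local({
  m <- matrix(-2, 5, 5, dimnames = list(c(.nucs, "N"), c(.nucs, "N")))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
})

#' Map a reference gene onto a genomic region
#'
#' Semi-global affine-gap alignment: the UTR-flanked reference aligns
#' globally, the region locally, on whichever strand scores better. N in
#' the region is a zero-score wildcard.
#'
#' @param reference a [reference_gene()].
#' @param region a `GenomicLocus` or nucleotide string.
#' @param min_coverage minimum fraction of the reference CDS aligned to
#'   region sequence for an ortholog call (default 0.2).
#' @param min_identity minimum nucleotide identity over the aligned
#'   (non-N) CDS columns (default 0.55): because the pattern aligns
#'   globally, unrelated sequence still reaches ~40-45% column identity
#'   under affine realignment, so coverage alone cannot reject it.
#' @param gap_opening,gap_extension affine gap penalties (defaults 12 / 3,
#'   tolerant of ~20% divergence).
#' @return a `MappedAlignment`: aligned reference/region strings, the
#'   strand used, per-column reference and region coordinates, the CDS
#'   span in reference coordinates, CDS coverage, unambiguous (non-N)
#'   CDS coverage, and the N fraction of region columns.
#' @export
map_reference_cds <- function(reference, region, min_coverage = 0.2,
                              min_identity = 0.55,
                              gap_opening = 12, gap_extension = 3) {
  stopifnot(inherits(reference, "ReferenceGene"))
  region_seq <- if (inherits(region, "GenomicLocus")) region$seq else region
  region_seq <- toupper(region_seq)
  if (nchar(region_seq) == 0L) stop("empty region")
  ref_full <- paste0(reference$utr5, reference$cds, reference$utr3)

  align_one <- function(subj) {
    Biostrings::pairwiseAlignment(
      pattern = ref_full, subject = subj, type = "global-local",
      substitutionMatrix = .map_submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
  }
  fwd <- align_one(region_seq)
  rev <- align_one(revcomp(region_seq))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  aln <- if (use_rev) rev else fwd
  subj_used <- if (use_rev) revcomp(region_seq) else region_seq

  ref_aln <- as.character(Biostrings::alignedPattern(aln))
  reg_aln <- as.character(Biostrings::alignedSubject(aln))
  rc <- strsplit(ref_aln, "")[[1L]]
  gc <- strsplit(reg_aln, "")[[1L]]
  ref_coord <- cumsum(rc != "-")
  ref_coord[rc == "-"] <- NA
  reg_start <- Biostrings::start(Biostrings::subject(aln))
  reg_coord <- reg_start - 1L + cumsum(gc != "-")
  reg_coord[gc == "-"] <- NA

  cds_span <- c(nchar(reference$utr5) + 1L,
                nchar(reference$utr5) + nchar(reference$cds))
  in_cds <- !is.na(ref_coord) & ref_coord >= cds_span[1] &
    ref_coord <= cds_span[2]
  covered <- in_cds & gc != "-"
  coverage <- sum(covered) / nchar(reference$cds)
  unamb_cols <- covered & gc %in% .nucs
  unamb <- sum(unamb_cols) / nchar(reference$cds)
  cds_identity <- if (any(unamb_cols))
    sum(rc[unamb_cols] == gc[unamb_cols]) / sum(unamb_cols) else 0
  if (coverage < min_coverage || cds_identity < min_identity)
    stop("no ortholog detected: reference CDS coverage ",
         sprintf("%.2f", coverage), " / identity ",
         sprintf("%.2f", cds_identity), " below floors (",
         min_coverage, " / ", min_identity, ")")

  structure(list(
    reference = reference, ref_aln = ref_aln, region_aln = reg_aln,
    strand = if (use_rev) "-" else "+", region_seq = subj_used,
    ref_coord = ref_coord, region_coord = reg_coord,
    cds_span = cds_span, coverage = coverage,
    unambiguous_coverage = unamb, cds_identity = cds_identity,
    n_fraction = mean(gc == "N"),
    score = Biostrings::score(aln)), class = "MappedAlignment")
}

#' @export
print.MappedAlignment <- function(x, ...) {
  cat(sprintf(paste0("MappedAlignment: %s vs region (%s strand), CDS ",
                     "coverage %.2f (unambiguous %.2f), N fraction %.3f\n"),
              x$reference$name, x$strand, x$coverage,
              x$unambiguous_coverage, x$n_fraction))
  invisible(x)
}

.empty_mutations <- function() {
  data.frame(kind = character(0), ref_coord = integer(0),
             length_nt = integer(0), codon_index = integer(0),
             orf_fraction = numeric(0), compensated = logical(0),
             region_coord = integer(0), ref_allele = character(0),
             alt_allele = character(0),
             read_validation_status = character(0),
             stringsAsFactors = FALSE)
}

.runs <- function(x) {
  # start/length of TRUE runs
  r <- rle(x)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  data.frame(start = s[r$values], len = r$lengths[r$values])
}

#' Call ORF-abolishing mutations from a mapped alignment
#'
#' Emits every alignment indel inside the reference CDS whose length is not
#' a multiple of 3 as a frameshift (coordinates left-aligned against the
#' reference), and every in-frame stop codon of the reconstructed target
#' sequence -- read in the running (shifted) frame -- upstream of the
#' reference terminal codon as a premature stop. Codons containing N or
#' spanning gaps are never counted as stops. Frameshift groups whose net
#' frame offset returns to zero are flagged `compensated` but still
#' reported.
#'
#' @param aln a [map_reference_cds()] result.
#' @return data frame of `InactivatingMutation` rows: kind, ref_coord
#'   (1-based reference-CDS position), length_nt, codon_index,
#'   orf_fraction, compensated, region_coord, ref_allele, alt_allele,
#'   read_validation_status.
#' @export
call_inactivating_mutations <- function(aln) {
  stopifnot(inherits(aln, "MappedAlignment"))
  rc <- strsplit(aln$ref_aln, "")[[1L]]
  gc <- strsplit(aln$region_aln, "")[[1L]]
  ncol_ <- length(rc)
  cds_lo <- aln$cds_span[1]
  cds_hi <- aln$cds_span[2]
  ref_cds <- substr(paste0(aln$reference$utr5, aln$reference$cds,
                           aln$reference$utr3), cds_lo, cds_hi)
  ncod <- nchar(ref_cds) %/% 3L
  to_cds <- function(coord) coord - cds_lo + 1L

  in_cds <- !is.na(aln$ref_coord) & aln$ref_coord >= cds_lo &
    aln$ref_coord <= cds_hi
  # a column belongs to the CDS window if it lies between the first and
  # last CDS-aligned columns (insertions inside the CDS have NA ref_coord)
  if (!any(in_cds)) return(.empty_mutations())
  first_col <- min(which(in_cds))
  last_col <- max(which(in_cds))
  window <- seq(first_col, last_col)

  rows <- list()

  # --- deletions: gap runs in the region over CDS columns ---
  # ref_coord is left-aligned against the reference (lesion identity is
  # coordinate-exact across taxa); region_coord and the alleles stay in the
  # original alignment columns, anchored on the region's own base, so the
  # mutant haplotype is literally present in the region for validation.
  del <- .runs(gc == "-" & seq_len(ncol_) %in% window & in_cds)
  if (nrow(del) > 0L) for (i in seq_len(nrow(del))) {
    cols <- del$start[i]:(del$start[i] + del$len[i] - 1L)
    start_cds <- to_cds(aln$ref_coord[cols[1L]])
    s <- left_align_deletion(ref_cds, start_cds, del$len[i])
    prev_cols <- which(!is.na(aln$region_coord) &
                         seq_len(ncol_) < cols[1L])
    anchor_col <- if (length(prev_cols)) max(prev_cols) else NA_integer_
    regc <- if (is.na(anchor_col)) NA_integer_
      else aln$region_coord[anchor_col]
    anchor_base <- if (is.na(anchor_col)) "" else gc[anchor_col]
    deleted <- substr(ref_cds, start_cds, start_cds + del$len[i] - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = if (del$len[i] %% 3L != 0L) "frameshift_deletion"
             else "inframe_deletion",
      ref_coord = s, length_nt = del$len[i],
      codon_index = (s - 1L) %/% 3L + 1L,
      orf_fraction = ((s - 1L) %/% 3L + 1L) / ncod,
      compensated = FALSE, region_coord = regc,
      ref_allele = paste0(anchor_base, deleted), alt_allele = anchor_base,
      read_validation_status = "unvalidated", stringsAsFactors = FALSE)
  }

  # --- insertions: gap runs in the reference strictly inside the CDS ---
  ins <- .runs(rc == "-" & seq_len(ncol_) %in% window)
  if (nrow(ins) > 0L) for (i in seq_len(nrow(ins))) {
    cols <- ins$start[i]:(ins$start[i] + ins$len[i] - 1L)
    prev_ref <- aln$ref_coord[seq_len(cols[1L] - 1L)]
    prev_ref <- prev_ref[!is.na(prev_ref)]
    pos_cds <- if (length(prev_ref)) to_cds(max(prev_ref)) else 0L
    inserted <- paste(gc[cols], collapse = "")
    if (grepl("-", inserted)) next
    la <- left_align_insertion(ref_cds, pos_cds, inserted)
    prev_cols <- which(!is.na(aln$region_coord) &
                         seq_len(ncol_) < cols[1L])
    anchor_col <- if (length(prev_cols)) max(prev_cols) else NA_integer_
    regc <- if (is.na(anchor_col)) NA_integer_
      else aln$region_coord[anchor_col]
    anchor_base <- if (is.na(anchor_col)) "" else gc[anchor_col]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = if (ins$len[i] %% 3L != 0L) "frameshift_insertion"
             else "inframe_insertion",
      ref_coord = la$pos, length_nt = ins$len[i],
      codon_index = max(la$pos - 1L, 0L) %/% 3L + 1L,
      orf_fraction = (max(la$pos - 1L, 0L) %/% 3L + 1L) / ncod,
      compensated = FALSE, region_coord = regc,
      ref_allele = anchor_base,
      alt_allele = paste0(anchor_base, inserted),
      read_validation_status = "unvalidated", stringsAsFactors = FALSE)
  }

  # --- premature stops ---
  # Stops are screened in two frames and the union reported: (a) the
  # running (shifted) frame of the reconstructed target, which is the
  # actual reading frame downstream of frameshifts, and (b) the reference
  # frame of the alignment (codons at reference codon positions aligned
  # 1:1), which is what alignment screening sees and which recovers stops
  # that an upstream frameshift has moved out of the reading frame.
  tgt_cols <- window[gc[window] != "-"]
  tgt <- gc[tgt_cols]
  ntgt <- length(tgt)
  k <- 1L
  while (k + 2L <= ntgt) {
    codon <- paste(tgt[k:(k + 2L)], collapse = "")
    if (codon %in% .stop_codons) {
      col1 <- tgt_cols[k]
      refc <- aln$ref_coord[col1]
      if (is.na(refc)) {
        prev <- aln$ref_coord[seq_len(col1)]
        prev <- prev[!is.na(prev)]
        refc <- if (length(prev)) max(prev) else cds_lo
      }
      ci <- (to_cds(refc) - 1L) %/% 3L + 1L
      if (ci < ncod) {
        exp_codon <- substr(ref_cds, 3L * (ci - 1L) + 1L, 3L * ci)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "premature_stop", ref_coord = 3L * (ci - 1L) + 1L,
          length_nt = NA_integer_, codon_index = ci,
          orf_fraction = ci / ncod, compensated = FALSE,
          region_coord = aln$region_coord[col1],
          ref_allele = exp_codon, alt_allele = codon,
          read_validation_status = "unvalidated", stringsAsFactors = FALSE)
      }
    }
    k <- k + 3L
  }

  # reference-frame scan: 1:1 aligned triplets at reference codon positions
  col_of_ref <- rep(NA_integer_, cds_hi)
  ok_cols <- which(!is.na(aln$ref_coord) & gc != "-")
  col_of_ref[aln$ref_coord[ok_cols]] <- ok_cols
  for (ci in seq_len(ncod - 1L)) {
    refpos <- cds_lo - 1L + (3L * (ci - 1L) + 1L):(3L * ci)
    if (max(refpos) > cds_hi) break
    cols <- col_of_ref[refpos]
    if (anyNA(cols)) next
    if (cols[3L] - cols[1L] != 2L) next   # indel inside the codon
    codon <- paste(gc[cols], collapse = "")
    if (codon %in% .stop_codons) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "premature_stop", ref_coord = 3L * (ci - 1L) + 1L,
        length_nt = NA_integer_, codon_index = ci,
        orf_fraction = ci / ncod, compensated = FALSE,
        region_coord = aln$region_coord[cols[1L]],
        ref_allele = substr(ref_cds, 3L * (ci - 1L) + 1L, 3L * ci),
        alt_allele = codon, read_validation_status = "unvalidated",
        stringsAsFactors = FALSE)
    }
  }

  if (length(rows) == 0L) return(.empty_mutations())
  out <- do.call(rbind, rows)
  dup_stop <- out$kind == "premature_stop" &
    duplicated(paste(out$kind, out$ref_coord))
  out <- out[!dup_stop, , drop = FALSE]
  # drop in-frame indels: they do not abolish the ORF
  out <- out[!out$kind %in% c("inframe_deletion", "inframe_insertion"), ,
             drop = FALSE]
  out <- out[order(out$ref_coord), , drop = FALSE]
  rownames(out) <- NULL

  # flag compensated frameshift groups (net offset back to 0 mod 3)
  fs <- grepl("^frameshift", out$kind)
  if (sum(fs) >= 2L) {
    sign <- ifelse(out$kind[fs] == "frameshift_insertion", 1L, -1L)
    off <- cumsum(sign * out$length_nt[fs])
    grp_start <- 1L
    for (j in seq_along(off)) {
      if (off[j] %% 3L == 0L) {
        if (j > grp_start) out$compensated[which(fs)[grp_start:j]] <- TRUE
        grp_start <- j + 1L
      }
    }
  }
  out
}

#' Detect a truncation by a sliding-window identity drop
#'
#' Percent identity of the reference/region alignment is computed in
#' windows; a truncation is called at the first transition from a window
#' at or above `high_thr` to below `low_thr` sustained for at least two
#' consecutive windows. Windows dominated by N are uninformative; if the
#' low-identity signal falls entirely in N-dominated windows the result is
#' inconclusive rather than a truncation.
#'
#' @param aln a [map_reference_cds()] result.
#' @param window_nt window width in alignment columns (>= 30, default 60).
#' @param step_nt step between windows (default 15).
#' @param high_thr,low_thr identity thresholds in percent (defaults 70/50: affine realignment keeps unrelated sequence near 40-45% identity, so the low threshold must sit above that band).
#' @return `NULL` when no truncation is found; otherwise a list with
#'   `breakpoint` (reference coordinate of the transition window start; NA
#'   when inconclusive) and `inconclusive`.
#' @export
detect_truncation <- function(aln, window_nt = 60L, step_nt = 15L,
                              high_thr = 70, low_thr = 50) {
  stopifnot(inherits(aln, "MappedAlignment"), window_nt >= 30L)
  rc <- strsplit(aln$ref_aln, "")[[1L]]
  gc <- strsplit(aln$region_aln, "")[[1L]]
  n <- length(rc)
  if (n < window_nt) {
    warning("alignment shorter than one window")
    return(NULL)
  }
  starts <- seq(1L, n - window_nt + 1L, by = step_nt)
  ident <- vapply(starts, function(s) {
    cols <- s:(s + window_nt - 1L)
    inf <- rc[cols] %in% .nucs & gc[cols] %in% .nucs
    if (sum(inf) < window_nt / 2) return(NA_real_)
    100 * sum(rc[cols][inf] == gc[cols][inf]) / sum(inf)
  }, numeric(1))

  k <- length(ident)
  seen_high <- FALSE
  for (i in seq_len(k - 1L)) {
    if (!is.na(ident[i]) && ident[i] >= high_thr) seen_high <- TRUE
    if (seen_high &&
        !is.na(ident[i]) && ident[i] < low_thr &&
        !is.na(ident[i + 1L]) && ident[i + 1L] < low_thr) {
      col <- starts[i]
      prev <- aln$ref_coord[seq_len(col)]
      prev <- prev[!is.na(prev)]
      bp <- if (length(prev)) max(prev) else NA_integer_
      return(list(breakpoint = bp, inconclusive = FALSE))
    }
  }
  if (anyNA(ident)) return(list(breakpoint = NA_integer_,
                                inconclusive = TRUE))
  NULL
}

#' Truncation record as a mutation-table row
#'
#' @param trunc a [detect_truncation()] result (non-inconclusive).
#' @param aln the alignment it came from.
#' @return a one-row data frame compatible with
#'   [call_inactivating_mutations()] output.
#' @export
truncation_as_mutation <- function(trunc, aln) {
  ncod <- nchar(aln$reference$cds) %/% 3L
  ref_cds_coord <- max(1L, trunc$breakpoint - aln$cds_span[1] + 1L)
  ci <- min((ref_cds_coord - 1L) %/% 3L + 1L, ncod)
  data.frame(kind = "truncation", ref_coord = ref_cds_coord,
             length_nt = NA_integer_, codon_index = ci,
             orf_fraction = ci / ncod, compensated = FALSE,
             region_coord = NA_integer_, ref_allele = NA_character_,
             alt_allele = NA_character_,
             read_validation_status = "unvalidated",
             stringsAsFactors = FALSE)
}

#' Classify the coding status of a mapped locus
#'
#' `inconclusive` when the unambiguous (non-N, aligned) coverage of the
#' reference CDS is below `min_unambiguous_coverage`; otherwise `eroded`
#' when at least one inactivating mutation (truncations count) was found;
#' otherwise `intact`.
#'
#' @param mutations mutation table (may include a truncation row).
#' @param aln a [map_reference_cds()] result.
#' @param min_unambiguous_coverage default 0.9.
#' @return one of `"intact"`, `"eroded"`, `"inconclusive"`.
#' @export
classify_coding_status <- function(mutations, aln,
                                   min_unambiguous_coverage = 0.9) {
  if (aln$unambiguous_coverage < min_unambiguous_coverage)
    return("inconclusive")
  if (!is.null(mutations) && nrow(mutations) > 0L) return("eroded")
  "intact"
}

#' Reconstruct a frame-corrected CDS from a mapped alignment
#'
#' One symbol per reference CDS position: the aligned region base where
#' present, `N` where the region is N, `?` where the region is deleted or
#' unaligned. Inserted region bases (reference gap columns) are omitted,
#' which restores the reference frame -- the input expected by
#' [translation_align()].
#'
#' @param aln a [map_reference_cds()] result.
#' @return nucleotide string of reference-CDS length.
#' @export
frame_corrected_cds <- function(aln) {
  rc <- strsplit(aln$ref_aln, "")[[1L]]
  gc <- strsplit(aln$region_aln, "")[[1L]]
  out <- rep("?", aln$cds_span[2] - aln$cds_span[1] + 1L)
  in_cds <- !is.na(aln$ref_coord) & aln$ref_coord >= aln$cds_span[1] &
    aln$ref_coord <= aln$cds_span[2]
  pos <- aln$ref_coord[in_cds] - aln$cds_span[1] + 1L
  ch <- gc[in_cds]
  ch[!ch %in% c(.nucs, "N")] <- "?"
  out[pos] <- ch
  paste(out, collapse = "")
}
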