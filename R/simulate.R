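# Ground-truth simulator: codon-model sequence evolution on a tree,
# injection of inactivating lesions, locus assembly between flank genes,
# and read simulation. Every randomized operation takes a mandatory seed
# and restores the caller's RNG state.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Specification of a codon-model simulation
#'
#' Bundles everything [simulate_cds_evolution()] needs: a rooted tree with
#' branch lengths in expected substitutions per codon, a per-branch omega
#' map, kappa, sense-codon equilibrium frequencies, the root coding
#' sequence, and a seed.
#'
#' @param tree rooted `phylo` with >= 2 leaves and branch lengths.
#' @param omega_by_branch single omega for all branches, or a named vector
#'   keyed by the child tip/node label of each branch (use a `.default`
#'   entry for unnamed branches).
#' @param kappa transition/transversion ratio, > 0.
#' @param codon_freqs 61 sense-codon frequencies (default uniform).
#' @param root_cds root coding sequence; length divisible by 3 and free of
#'   internal stop codons.
#' @param seed integer seed (mandatory).
#' @return an `EvolutionSpec`.
#' @export
evolution_spec <- function(tree, omega_by_branch, kappa, root_cds, seed,
                           codon_freqs = NULL) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2L,
            !is.null(tree$edge.length), kappa > 0, all(omega_by_branch >= 0))
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61)
  if (abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon_freqs must sum to 1")
  root_cds <- toupper(root_cds)
  cods <- .split_codons(root_cds)
  if (any(cods %in% .stop_codons))
    stop("root_cds contains an internal stop codon at codon ",
         which(cods %in% .stop_codons)[1L])
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(tree = tree, omega_by_branch = omega_by_branch,
                 kappa = kappa, codon_freqs = codon_freqs,
                 root_cds = root_cds, seed = as.integer(seed)),
            class = "EvolutionSpec")
}

.edge_omegas <- function(tree, omega_by_branch) {
  E <- nrow(tree$edge)
  if (length(omega_by_branch) == 1L && is.null(names(omega_by_branch)))
    return(rep(unname(omega_by_branch), E))
  labs <- c(tree$tip.label,
            tree$node.label %||% rep("", tree$Nnode))
  child_lab <- labs[tree$edge[, 2]]
  om <- unname(omega_by_branch[child_lab])
  if (anyNA(om)) {
    if (!".default" %in% names(omega_by_branch))
      stop("omega_by_branch misses branches (children: ",
           paste(unique(child_lab[is.na(om)]), collapse = ", "),
           ") and has no .default")
    om[is.na(om)] <- omega_by_branch[[".default"]]
  }
  om
}

#' Simulate coding-sequence evolution under the GY94 process
#'
#' Starting from the root CDS, each branch evolves every codon site by the
#' exact transition matrix expm(Q t) of its omega category (no event-level
#' simulation); stop codons are never created because the state space is
#' the 61 sense codons.
#'
#' @param spec an [evolution_spec()].
#' @return list with `cds` (named nucleotide strings, one per leaf),
#'   `alignment` (the true [codon_alignment()], gap-free), and
#'   `node_states` (codon-state matrix for all nodes).
#' @export
simulate_cds_evolution <- function(spec) {
  stopifnot(inherits(spec, "EvolutionSpec"))
  tr <- spec$tree
  ns <- length(.split_codons(spec$root_cds))
  root_state <- codon_index(.split_codons(spec$root_cds))
  if (anyNA(root_state)) stop("root_cds contains a stop codon")
  pi <- spec$codon_freqs
  om <- .edge_omegas(tr, spec$omega_by_branch)
  ntip <- length(tr$tip.label)
  N <- ntip + tr$Nnode
  states <- matrix(NA_integer_, N, ns)
  root <- ntip + 1L
  states[root, ] <- root_state

  # one transition matrix per distinct (omega, t); sampled top-down
  ord <- rev(ape::reorder.phylo(tr, "postorder", index.only = TRUE))
  with_seed(spec$seed, {
    Qcache <- list()
    for (e in ord) {
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      if (t <= 0) {
        states[child, ] <- states[parent, ]
        next
      }
      key <- sprintf("%.12g", om[e])
      if (is.null(Qcache[[key]]))
        Qcache[[key]] <- gy94_eigen(
          gy94_rate_matrix(spec$kappa, om[e], pi), pi)
      eg <- Qcache[[key]]
      P <- eg$A %*% (exp(eg$lambda * t) * eg$B)
      P[P < 0] <- 0
      ps <- states[parent, ]
      cs <- integer(ns)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(61L, length(idx), replace = TRUE,
                              prob = P[s, ])
      }
      states[child, ] <- cs
    }
  })
  leaf_codons <- matrix(.codons[states[seq_len(ntip), , drop = FALSE]],
                        nrow = ntip, dimnames = list(tr$tip.label, NULL))
  cds <- apply(leaf_codons, 1L, paste0, collapse = "")
  list(cds = cds, alignment = codon_alignment(leaf_codons),
       node_states = states)
}

#' Specification of an inactivating lesion
#'
#' @param kind `"deletion"`, `"insertion"` or `"nonsense"`.
#' @param position_frac where along the CDS to place the lesion, in \[0, 1\].
#' @param length_nt indel length (default 2 for deletions, 1 for
#'   insertions; absent for nonsense lesions).
#' @param branch optional branch identifier used by higher-level fixtures.
#' @return a `LesionSpec`.
#' @export
lesion_spec <- function(kind, position_frac, length_nt = NULL,
                        branch = NULL) {
  kind <- match.arg(kind, c("deletion", "insertion", "nonsense"))
  stopifnot(position_frac >= 0, position_frac <= 1)
  if (kind == "nonsense") {
    if (!is.null(length_nt)) stop("nonsense lesions have no length_nt")
  } else {
    if (is.null(length_nt))
      length_nt <- if (kind == "deletion") 2L else 1L
    stopifnot(length_nt >= 1L)
  }
  structure(list(kind = kind, position_frac = position_frac,
                 length_nt = length_nt, branch = branch),
            class = "LesionSpec")
}

# Left-align an indel against the reference context (VCF-style), so that
# injected truth and alignment-derived calls share one coordinate
# convention in repetitive sequence.
left_align_deletion <- function(ref, start, len) {
  chars <- strsplit(ref, "")[[1L]]
  while (start > 1L && chars[start - 1L] == chars[start + len - 1L])
    start <- start - 1L
  start
}

left_align_insertion <- function(ref, pos, ins) {
  chars <- strsplit(ref, "")[[1L]]
  ic <- strsplit(ins, "")[[1L]]
  L <- length(ic)
  while (pos > 0L && chars[pos] == ic[L]) {
    ic <- c(chars[pos], ic[-L])
    pos <- pos - 1L
  }
  list(pos = pos, ins = paste(ic, collapse = ""))
}

.nearest_stop <- function(codon) {
  # stop codon reachable with fewest substitutions; ties resolved in the
  # order TAA, TAG, TGA
  d <- vapply(.stop_codons, function(s) {
    sum(strsplit(codon, "")[[1L]] != strsplit(s, "")[[1L]])
  }, numeric(1))
  .stop_codons[which.min(d)]
}

#' Inject inactivating lesions into a coding sequence
#'
#' Lesions are resolved to integer coordinates on the input (reference)
#' sequence and applied left-to-right with coordinate bookkeeping. Nonsense
#' lesions overwrite the codon at `floor(position_frac * n_codons)` with
#' the stop codon reachable by the fewest substitutions (ties: TAA).
#' Indel truth coordinates are left-aligned against the reference context.
#'
#' @param cds the input coding sequence (nucleotide string).
#' @param lesions list of [lesion_spec()] objects.
#' @param seed integer seed (drives inserted-base content).
#' @return list with `seq` (mutated sequence) and `truth` (data frame:
#'   kind, ref_coord, length_nt, codon_index, inserted).
#' @export
inject_lesions <- function(cds, lesions, seed = 1L) {
  cds <- toupper(cds)
  n <- nchar(cds)
  ncod <- n %/% 3L
  if (length(lesions) == 0L)
    return(list(seq = cds, truth = .empty_truth()))
  if (inherits(lesions, "LesionSpec")) lesions <- list(lesions)

  resolved <- with_seed(seed, lapply(lesions, function(l) {
    if (l$kind == "nonsense") {
      ci <- min(max(floor(l$position_frac * ncod), 0L) + 1L, ncod)
      start <- 3L * (ci - 1L) + 1L
      old <- substr(cds, start, start + 2L)
      list(kind = "nonsense", start = start, end = start + 2L,
           codon_index = ci, new = .nearest_stop(old), len = NA_integer_,
           ins = NA_character_)
    } else if (l$kind == "deletion") {
      start <- min(max(floor(l$position_frac * n), 0L) + 1L,
                   n - l$length_nt + 1L)
      list(kind = "deletion", start = start,
           end = start + l$length_nt - 1L, len = l$length_nt,
           codon_index = (start - 1L) %/% 3L + 1L, ins = NA_character_)
    } else {
      pos <- min(max(floor(l$position_frac * n), 0L), n)  # insert after pos
      ins <- paste(sample(.nucs, l$length_nt, replace = TRUE),
                   collapse = "")
      list(kind = "insertion", start = pos, end = pos, len = l$length_nt,
           codon_index = max(pos - 1L, 0L) %/% 3L + 1L, ins = ins)
    }
  }))

  ord <- order(vapply(resolved, `[[`, numeric(1), "start"))
  resolved <- resolved[ord]
  starts <- vapply(resolved, `[[`, numeric(1), "start")
  ends <- vapply(resolved, `[[`, numeric(1), "end")
  if (length(resolved) > 1L &&
      any(starts[-1L] <= ends[-length(ends)]))
    stop("overlapping lesions")

  out <- cds
  offset <- 0L
  rows <- list()
  for (l in resolved) {
    if (l$kind == "nonsense") {
      substr(out, l$start + offset, l$end + offset) <- l$new
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "premature_stop", ref_coord = l$start,
        length_nt = NA_integer_, codon_index = l$codon_index,
        inserted = NA_character_, mut_coord = l$start + offset,
        stringsAsFactors = FALSE)
    } else if (l$kind == "deletion") {
      s <- left_align_deletion(cds, l$start, l$len)
      out <- paste0(substr(out, 1L, s + offset - 1L),
                    substring(out, s + offset + l$len))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "frameshift_deletion", ref_coord = s, length_nt = l$len,
        codon_index = (s - 1L) %/% 3L + 1L, inserted = NA_character_,
        mut_coord = s + offset, stringsAsFactors = FALSE)
      offset <- offset - l$len
    } else {
      la <- left_align_insertion(cds, l$start, l$ins)
      out <- paste0(substr(out, 1L, la$pos + offset),
                    la$ins, substring(out, la$pos + offset + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "frameshift_insertion", ref_coord = la$pos,
        length_nt = l$len, codon_index = max(la$pos - 1L, 0L) %/% 3L + 1L,
        inserted = la$ins, mut_coord = la$pos + offset + 1L,
        stringsAsFactors = FALSE)
      offset <- offset + l$len
    }
  }
  truth <- do.call(rbind, rows)
  truth <- truth[order(truth$ref_coord), , drop = FALSE]
  rownames(truth) <- NULL
  list(seq = out, truth = truth)
}

.empty_truth <- function() {
  data.frame(kind = character(0), ref_coord = integer(0),
             length_nt = integer(0), codon_index = integer(0),
             inserted = character(0), mut_coord = integer(0),
             stringsAsFactors = FALSE)
}

.random_dna <- function(n) {
  paste(sample(.nucs, n, replace = TRUE), collapse = "")
}

#' Assemble a genomic locus around a coding sequence
#'
#' Places the CDS between flank genes separated by random intergenic
#' spacers, optionally masks intervals with N runs, and optionally emits
#' the reverse complement (negative strand).
#'
#' @param cds coding sequence (possibly lesioned).
#' @param flank_genes list with `upstream` and `downstream` named character
#'   vectors of flank-gene sequences, ordered from outermost to innermost
#'   on the upstream side and innermost to outermost downstream. May be
#'   empty.
#' @param intergenic_length spacer length between consecutive features
#'   (recycled), default 300.
#' @param n_runs data frame with columns `at` (fractional position),
#'   `length` (nt) and `relative_to` (`"cds"` or `"locus"`); the named
#'   interval is overwritten with N.
#' @param strand `"+"` or `"-"`.
#' @param fragment_cds allow N runs to overlap the CDS (default FALSE:
#'   overlap is an error).
#' @param seed integer seed for spacer sequence content.
#' @param name locus name.
#' @return list with `locus` (a `GenomicLocus`: name, seq, strand,
#'   n_runs, cds_interval, flank_coords) and `truth` (a `LocusTruth`
#'   mirror used by tests).
#' @export
build_locus <- function(cds, flank_genes = list(), intergenic_length = 300L,
                        n_runs = NULL, strand = "+", fragment_cds = FALSE,
                        seed = 1L, name = "locus") {
  up <- flank_genes$upstream %||% character(0)
  down <- flank_genes$downstream %||% character(0)
  feats <- c(as.list(up), list(CDS = cds), as.list(down))
  k <- length(feats)
  spacer_len <- rep_len(intergenic_length, max(k - 1L, 0L))
  with_seed(seed, {
    parts <- character(0)
    coords <- data.frame(feature = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
    pos <- 0L
    for (i in seq_len(k)) {
      s <- feats[[i]]
      parts <- c(parts, s)
      coords <- rbind(coords, data.frame(
        feature = names(feats)[i], start = pos + 1L,
        end = pos + nchar(s), stringsAsFactors = FALSE))
      pos <- pos + nchar(s)
      if (i < k) {
        sp <- .random_dna(spacer_len[i])
        parts <- c(parts, sp)
        pos <- pos + spacer_len[i]
      }
    }
    seq <- paste(parts, collapse = "")
  })
  cds_iv <- coords[coords$feature == "CDS", c("start", "end")]

  nr_abs <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(n_runs) && nrow(n_runs) > 0L) {
    for (i in seq_len(nrow(n_runs))) {
      rel <- if (is.null(n_runs$relative_to)) "cds" else n_runs$relative_to[i]
      if (rel == "cds") {
        s <- cds_iv$start + floor(n_runs$at[i] * nchar(cds))
      } else {
        s <- 1L + floor(n_runs$at[i] * nchar(seq))
      }
      e <- min(s + n_runs$length[i] - 1L, nchar(seq))
      overlaps_cds <- s <= cds_iv$end && e >= cds_iv$start
      if (overlaps_cds && !fragment_cds)
        stop("N run overlaps the CDS; set fragment_cds = TRUE to allow")
      substr(seq, s, e) <- paste(rep("N", e - s + 1L), collapse = "")
      nr_abs <- rbind(nr_abs, data.frame(start = s, end = e))
    }
  }

  if (strand == "-") seq <- revcomp(seq)
  locus <- structure(list(name = name, seq = unname(seq), strand = strand,
                          cds_interval = as.integer(unlist(cds_iv)),
                          flank_coords = coords, n_runs = nr_abs),
                     class = "GenomicLocus")
  truth <- structure(list(cds = cds, cds_interval = locus$cds_interval,
                          flank_coords = coords, n_runs = nr_abs,
                          strand = strand),
                     class = "LocusTruth")
  list(locus = locus, truth = truth)
}

#' @export
print.GenomicLocus <- function(x, ...) {
  cat(sprintf("GenomicLocus %s: %d nt (%s strand), CDS at %d-%d, %d N run(s)\n",
              x$name, nchar(x$seq), x$strand, x$cds_interval[1],
              x$cds_interval[2], nrow(x$n_runs)))
  invisible(x)
}

#' Simulate sequencing reads from a locus
#'
#' Uniform start positions, substitution-only errors, random read strand,
#' and optional sampling from a mixture of alleles (e.g. a heterozygous
#' wild-type/mutant locus).
#'
#' @param locus a `GenomicLocus` or nucleotide string; when `allele_mix` is
#'   given, `alleles` must name the alternative sequences.
#' @param depth target mean per-base coverage, > 0.
#' @param read_len read length; must not exceed the (shortest) allele.
#' @param error_rate per-base substitution error probability.
#' @param allele_mix named fractions summing to 1 (default: single allele).
#' @param alleles named character vector of allele sequences (defaults to
#'   the locus sequence for every `allele_mix` name).
#' @param seed integer seed (mandatory).
#' @return list with `reads` (named character vector) and `truth`
#'   (data frame: read, allele, start, strand).
#' @export
simulate_reads <- function(locus, depth, read_len, error_rate = 0,
                           allele_mix = NULL, alleles = NULL, seed = 1L) {
  seq <- if (inherits(locus, "GenomicLocus")) locus$seq else locus
  if (is.null(allele_mix)) allele_mix <- c(ref = 1)
  if (is.null(alleles)) {
    alleles <- stats::setNames(rep(seq, length(allele_mix)),
                               names(allele_mix))
  }
  stopifnot(depth > 0, abs(sum(allele_mix) - 1) < 1e-9,
            all(names(allele_mix) %in% names(alleles)))
  if (read_len > min(nchar(alleles)))
    stop("read_len exceeds allele length")
  n_reads <- max(1L, round(depth * nchar(seq) / read_len))
  with_seed(seed, {
    # exact mixture proportions (the mix is a population fraction, not a
    # sampling probability); read positions remain random
    cnt <- round(allele_mix * n_reads)
    cnt[1L] <- n_reads - sum(cnt[-1L])
    alle <- sample(rep(names(allele_mix), pmax(cnt, 0L)))
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    src_len <- nchar(alleles)[alle]
    starts <- 1L + floor(stats::runif(n_reads) * (src_len - read_len + 1L))
    reads <- substring(alleles[alle], starts, starts + read_len - 1L)
    if (error_rate > 0) {
      hit <- which(stats::runif(n_reads * read_len) < error_rate)
      if (length(hit) > 0L) {
        ri <- (hit - 1L) %/% read_len + 1L
        pos <- (hit - 1L) %% read_len + 1L
        for (k in seq_along(hit)) {
          b <- substr(reads[ri[k]], pos[k], pos[k])
          substr(reads[ri[k]], pos[k], pos[k]) <-
            sample(setdiff(.nucs, b), 1L)
        }
      }
    }
    minus <- strands == "-"
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
  })
  names(reads) <- sprintf("read_%05d", seq_len(n_reads))
  list(reads = reads,
       truth = data.frame(read = names(reads), allele = alle,
                          start = starts, strand = strands,
                          stringsAsFactors = FALSE))
}
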