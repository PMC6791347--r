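# Independent oracles and small generators shared across tests. These
# deliberately avoid the package's pruning / Dollo code paths: likelihoods
# are computed by exhaustive enumeration over internal-node states, loss
# counts by enumeration over Dollo-consistent origin assignments.

NUCS <- c("A", "C", "G", "T")

# exhaustive-enumeration log-likelihood for a rooted tree with <= 4 tips;
# states: integer matrix (tips x sites), NA = fully ambiguous. The sum
# runs over every joint assignment of internal-node states (61^nnode
# terms per site), vectorized over assignments -- no pruning involved.
brute_force_loglik <- function(tree, states, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  P <- lapply(tree$edge.length, function(t) gy94_transition_matrix(Q, t, pi))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  site_ll <- vapply(seq_len(ncol(states)), function(s) {
    w <- pi[combos[, 1L]]     # root = ntip + 1 is the first internal node
    for (e in seq_len(nrow(edge))) {
      pstates <- combos[, edge[e, 1L] - ntip]
      ch <- edge[e, 2L]
      if (ch <= ntip) {
        tip <- states[ch, s]
        if (!is.na(tip)) w <- w * P[[e]][cbind(pstates, tip)]
      } else {
        w <- w * P[[e]][cbind(pstates, combos[, ch - ntip])]
      }
    }
    log(sum(w))
  }, numeric(1))
  sum(site_ll)
}

random_codon_states <- function(ntip, nsites, amb_frac = 0.1) {
  st <- matrix(sample.int(61L, ntip * nsites, replace = TRUE), ntip, nsites)
  st[stats::runif(ntip * nsites) < amb_frac] <- NA
  st
}

states_to_alignment <- function(states, taxa) {
  m <- matrix(sense_codons()[states], nrow(states), ncol(states))
  m[is.na(m)] <- "???"
  rownames(m) <- taxa
  codon_alignment(m)
}

random_rooted_tree <- function(ntip, t_range = c(0.05, 0.5)) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), t_range[1], t_range[2])
  tr
}

# Dollo oracle: minimum number of inactivation branches over all
# origin assignments consistent with single-origin, no-reversal lesions.
# mat: lesions x taxa (1/0/NA); tree small (<= 6 tips).
dollo_oracle_count <- function(mat, tree) {
  ntip <- length(tree$tip.label)
  E <- nrow(tree$edge)
  tips_below <- lapply(seq_len(E), function(e) {
    node <- tree$edge[e, 2]
    if (node <= ntip) tree$tip.label[node]
    else tree$tip.label[ape::prop.part(tree)[[node - ntip]]]
  })
  lesion_options <- lapply(seq_len(nrow(mat)), function(r) {
    carriers <- colnames(mat)[which(mat[r, ] == 1L)]
    known <- colnames(mat)[which(!is.na(mat[r, ]))]
    if (length(carriers) == 0L) return(list(integer(0)))
    valid_edge <- vapply(seq_len(E), function(e) {
      kb <- intersect(tips_below[[e]], known)
      length(kb) > 0L && all(kb %in% carriers)
    }, logical(1))
    ve <- which(valid_edge)
    opts <- list()
    for (sz in seq_along(ve)) {
      for (idx in utils::combn(seq_along(ve), sz, simplify = FALSE)) {
        comb <- ve[idx]
        below <- unlist(tips_below[comb])
        if (anyDuplicated(below)) next            # overlapping origins
        if (!all(carriers %in% below)) next       # must cover every carrier
        opts[[length(opts) + 1L]] <- comb
      }
    }
    opts
  })
  eroded <- colnames(mat)[colSums(mat == 1L, na.rm = TRUE) > 0L]
  root_paths <- lapply(eroded, function(tx) {
    node <- match(tx, tree$tip.label)
    path <- integer(0)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0L) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
  count_for <- function(assignment) {
    les_edges <- unique(unlist(assignment))
    evs <- vapply(root_paths, function(path) {
      on <- intersect(path, les_edges)
      if (length(on) == 0L) return(NA_integer_)
      on[which.max(match(on, path))]
    }, integer(1))
    length(unique(evs[!is.na(evs)]))
  }
  best <- Inf
  grid <- expand.grid(lapply(lesion_options, seq_along))
  for (r in seq_len(nrow(grid))) {
    assignment <- lapply(seq_along(lesion_options), function(i)
      lesion_options[[i]][[grid[r, i]]])
    best <- min(best, count_for(assignment))
  }
  best
}

random_dna_str <- function(n) paste(sample(NUCS, n, replace = TRUE),
                                    collapse = "")

# a small reference, shared by annotation tests
make_test_reference <- function(n_codons = 200, seed = 1) {
  root <- geneloss:::random_root_cds(n_codons, seed)
  set.seed(seed + 1000)
  reference_gene(paste0(root, "TAA"),
                 utr5 = random_dna_str(100), utr3 = random_dna_str(100))
}
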