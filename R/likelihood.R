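# Likelihood of a codon alignment under the branch-category GY94 model.
# The heavy lifting (pruning, branch-length derivatives) is in C++; this
# file prepares the spectral factors, site patterns and edge orderings.

# Compress alignment columns into unique site patterns.
# Returns list(states = ntaxa x npattern integer matrix (0 = ambiguous),
#              weights, taxa).
.site_patterns <- function(aln) {
  m <- aln$codons
  st <- codon_index(m)
  st[is.na(st)] <- 0L
  st <- matrix(st, nrow = nrow(m), dimnames = dimnames(m))
  key <- apply(st, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(states = st[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]),
       taxa = rownames(m))
}

# Postorder edge permutation and category codes for a LabeledTree.
.tree_plumbing <- function(ltree) {
  tr <- ltree$tree
  ord <- ape::reorder.phylo(tr, "postorder", index.only = TRUE)
  lev <- unique(ltree$categories)
  list(tree = tr,
       edge = tr$edge[ord, , drop = FALSE],
       edge_len = tr$edge.length[ord],
       edge_cat = match(ltree$categories, lev)[ord],
       cat_levels = lev,
       order = ord)
}

# Spectral factors for each category given kappa and per-category omega.
.category_eigens <- function(kappa, omega_by_level, pi) {
  C <- length(omega_by_level)
  A <- array(0, c(61, 61, C))
  B <- array(0, c(61, 61, C))
  lam <- matrix(0, 61, C)
  for (k in seq_len(C)) {
    Q <- gy94_rate_matrix(kappa, omega_by_level[k], pi)
    e <- gy94_eigen(Q, pi)
    A[, , k] <- e$A
    B[, , k] <- e$B
    lam[, k] <- e$lambda
  }
  list(A = A, B = B, lambda = lam)
}

.loglik_core <- function(pat, plumbing, eigs, edge_len, pi,
                         want_grad = FALSE) {
  idx <- match(plumbing$tree$tip.label, pat$taxa)
  tipmat <- matrix(0L, length(idx), ncol(pat$states))
  has <- !is.na(idx)
  tipmat[has, ] <- pat$states[idx[has], , drop = FALSE]
  pruning_loglik(plumbing$edge, edge_len, plumbing$edge_cat,
                 eigs$A, eigs$B, eigs$lambda, tipmat, pat$weights, pi,
                 plumbing$tree$Nnode, want_grad)
}

#' Log-likelihood of a codon alignment on a labeled tree
#'
#' Felsenstein pruning over the 61 sense-codon states; each branch uses the
#' omega of its category. Codons containing gaps, N or ? (including stop
#' codons recorded as missing) are fully ambiguous: their tip partial
#' likelihood is 1 for all 61 states, so such sites are included rather
#' than dropped.
#'
#' @param aln a [codon_alignment()].
#' @param ltree a [labeled_tree()] whose tips cover the alignment taxa and
#'   whose edge lengths are in expected substitutions per codon.
#' @param params list with `kappa`, `omega` (named by category, or a single
#'   value), and optionally `codon_freqs` (61-vector; default
#'   [f3x4_frequencies()] of the alignment).
#' @return the log-likelihood (numeric scalar), with attribute
#'   `"site_loglik"` giving per-pattern log-likelihoods.
#' @export
codon_log_likelihood <- function(aln, ltree, params) {
  taxa <- rownames(aln$codons)
  if (!all(taxa %in% ltree$tree$tip.label))
    stop("alignment taxa missing from tree: ",
         paste(setdiff(taxa, ltree$tree$tip.label), collapse = ", "))
  pi <- params$codon_freqs
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  if (length(ltree$tree$tip.label) == 1L) {
    st <- codon_index(aln$codons[1L, ])
    ll <- sum(ifelse(is.na(st), 0, log(pi[st])))
    return(ll)
  }
  pat <- .site_patterns(aln)
  pl <- .tree_plumbing(ltree)
  om <- params$omega
  if (is.null(names(om)) && length(om) == 1L)
    om <- stats::setNames(rep(om, length(pl$cat_levels)), pl$cat_levels)
  if (!all(pl$cat_levels %in% names(om)))
    stop("params$omega must name every category: ",
         paste(setdiff(pl$cat_levels, names(om)), collapse = ", "))
  eigs <- .category_eigens(params$kappa, om[pl$cat_levels], pi)
  res <- .loglik_core(pat, pl, eigs, pl$edge_len, pi)
  if (!is.finite(res$loglik))
    stop("non-finite log-likelihood (check branch lengths and frequencies)")
  structure(res$loglik, site_loglik = res$site_loglik,
            pattern_weights = pat$weights)
}
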