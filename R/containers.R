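#' Gap-aware codon alignment
#'
#' A codon alignment is a taxa x codon-site character matrix whose cells are
#' 3-letter strings: a sense codon, `"---"` (gap), `"???"` (missing, e.g. a
#' stop codon recorded as missing), or any triplet containing `N`. All
#' non-sense-codon cells are treated as fully ambiguous by the likelihood
#' machinery.
#'
#' @param codons character matrix of 3-letter strings with taxon rownames.
#' @return an object of class `CodonAlignment`.
#' @export
codon_alignment <- function(codons) {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons))) stop("codon matrix needs taxon rownames")
  if (any(nchar(codons) != 3L)) stop("all cells must be 3-letter strings")
  structure(list(codons = codons), class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat("CodonAlignment:", nrow(x$codons), "taxa x", ncol(x$codons),
      "codon sites\n")
  amb <- mean(is.na(codon_index(x$codons)))
  cat(sprintf("  ambiguous cells: %.1f%%\n", 100 * amb))
  invisible(x)
}

#' @export
dim.CodonAlignment <- function(x) dim(x$codons)

#' Read / write a codon alignment as FASTA
#'
#' Sequences are the concatenated codons; `-` marks gap columns and `?`
#' missing data. Sequence lengths must be multiples of 3.
#'
#' @param path FASTA file.
#' @rdname codon_alignment_io
#' @export
read_codon_alignment <- function(path) {
  seqs <- read_fasta(path)
  n <- unique(nchar(seqs))
  if (length(n) != 1L || n %% 3L != 0L)
    stop("alignment sequences must share a length divisible by 3")
  m <- t(vapply(seqs, function(s) {
    substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  }, character(n / 3L)))
  rownames(m) <- names(seqs)
  codon_alignment(m)
}

#' @param aln a `CodonAlignment`.
#' @rdname codon_alignment_io
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1L, paste0, collapse = "")
  write_fasta(seqs, path)
  invisible(path)
}

#' Pairwise identity of an alignment
#'
#' Mean over taxon pairs of the fraction of columns, unambiguous in both
#' sequences, at which the two codons are identical.
#'
#' @param aln a `CodonAlignment`.
#' @return average pairwise identity in \[0, 1\].
#' @export
average_pairwise_identity <- function(aln) {
  m <- aln$codons
  ok <- matrix(!is.na(codon_index(m)), nrow(m), ncol(m))
  n <- nrow(m)
  if (n < 2L) return(1)
  tot <- 0; cnt <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    if (any(use)) {
      tot <- tot + mean(m[i, use] == m[j, use])
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

#' Rooted tree with branch categories
#'
#' Wraps an `ape` phylo tree together with one category label per edge
#' (following `tree$edge` row order). Categories partition the branches and
#' drive the per-branch omega of the codon model.
#'
#' @param tree a rooted `phylo` object with edge lengths.
#' @param categories character/factor of length `nrow(tree$edge)`.
#' @return an object of class `LabeledTree`.
#' @export
labeled_tree <- function(tree, categories) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  categories <- as.character(categories)
  if (length(categories) == 1L)
    categories <- rep(categories, nrow(tree$edge))
  if (length(categories) != nrow(tree$edge))
    stop("need one category per edge")
  structure(list(tree = tree, categories = categories),
            class = "LabeledTree")
}

#' @export
print.LabeledTree <- function(x, ...) {
  cat("LabeledTree:", length(x$tree$tip.label), "tips,",
      nrow(x$tree$edge), "branches\n")
  print(table(x$categories))
  invisible(x)
}

# --- branch selectors ------------------------------------------------------

.mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tips not in tree: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

.clade_edges <- function(tree, node) {
  # all edges within the clade rooted at `node` (excluding its stem)
  desc <- node
  res <- integer(0)
  repeat {
    e <- which(tree$edge[, 1] %in% desc & !(seq_len(nrow(tree$edge)) %in% res))
    if (length(e) == 0L) break
    res <- c(res, e)
    desc <- tree$edge[e, 2]
  }
  sort(res)
}

#' Branch selectors for category schemes
#'
#' Selectors describe sets of branches by clades, stems or tips; a scheme is
#' an ordered named list of selectors, applied in order (later selectors
#' override earlier ones), that must jointly cover every branch.
#'
#' `sel_clade(tips)` selects every branch inside the smallest clade
#' containing `tips` (optionally also its stem); `sel_stem(tips)` selects
#' just the stem branch of that clade; `sel_tips(labels)` the terminal
#' branches of the named taxa; `sel_rest()` all branches (use it first as
#' the background).
#'
#' @param tips,labels tip labels.
#' @param include_stem also include the clade's stem branch.
#' @return a branch selector object.
#' @export
sel_clade <- function(tips, include_stem = FALSE) {
  structure(list(type = "clade", tips = tips, include_stem = include_stem),
            class = "branch_selector")
}

#' @rdname sel_clade
#' @export
sel_stem <- function(tips) {
  structure(list(type = "stem", tips = tips), class = "branch_selector")
}

#' @rdname sel_clade
#' @export
sel_tips <- function(labels) {
  structure(list(type = "tips", tips = labels), class = "branch_selector")
}

#' @rdname sel_clade
#' @export
sel_rest <- function() {
  structure(list(type = "rest"), class = "branch_selector")
}

.select_edges <- function(tree, sel) {
  switch(sel$type,
    rest = seq_len(nrow(tree$edge)),
    tips = {
      idx <- match(sel$tips, tree$tip.label)
      if (anyNA(idx)) stop("selector names unknown tips: ",
                           paste(sel$tips[is.na(idx)], collapse = ", "))
      match(idx, tree$edge[, 2])
    },
    stem = {
      node <- .mrca_node(tree, sel$tips)
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0L) stop("selector matches no branch (clade is root)")
      e
    },
    clade = {
      node <- .mrca_node(tree, sel$tips)
      e <- .clade_edges(tree, node)
      if (sel$include_stem) e <- c(which(tree$edge[, 2] == node), e)
      if (length(e) == 0L) stop("selector matches no branch")
      e
    },
    stop("unknown selector type: ", sel$type))
}

#' Assign branch categories on a tree
#'
#' Applies a named scheme of [branch selectors][sel_clade] in order; every
#' branch must end up with exactly one category. Optionally takes the loss
#' [event set][count_independent_losses] for reporting which categories are
#' post-inactivation.
#'
#' @param tree rooted `phylo`.
#' @param scheme ordered named list of selectors; apply `sel_rest()` first
#'   as the background category.
#' @param event_set optional `LossEventSet` attached for reporting.
#' @return a [labeled_tree()].
#' @export
label_branch_categories <- function(tree, scheme, event_set = NULL) {
  stopifnot(is.list(scheme), !is.null(names(scheme)))
  cat <- rep(NA_character_, nrow(tree$edge))
  for (nm in names(scheme)) {
    e <- .select_edges(tree, scheme[[nm]])
    cat[e] <- nm
  }
  if (anyNA(cat))
    stop("scheme does not cover all branches; start with sel_rest()")
  lt <- labeled_tree(tree, cat)
  lt$event_set <- event_set
  lt
}

# --- Newick I/O with codeml-style #k tags ----------------------------------

#' Write / read a labeled tree with #k category tags
#'
#' Categories are encoded codeml-style: the background (first) category is
#' untagged, others append `#k` to the child tip/node label of each branch.
#'
#' @param ltree a `LabeledTree`.
#' @param path Newick file.
#' @rdname labeled_tree_io
#' @export
write_labeled_tree <- function(ltree, path) {
  tr <- ltree$tree
  lev <- unique(ltree$categories)
  code <- match(ltree$categories, lev) - 1L
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  for (e in which(code > 0L)) {
    child <- tr$edge[e, 2]
    if (child <= ntip)
      tr$tip.label[child] <- paste0(tr$tip.label[child], "#", code[e])
    else
      tr$node.label[child - ntip] <- paste0(tr$node.label[child - ntip],
                                            "#", code[e])
  }
  ape::write.tree(tr, file = path)
  writeLines(paste0("# categories: ",
                    paste(sprintf("%s=#%d", lev, seq_along(lev) - 1L),
                          collapse = " ")),
             con = sub("\\.nwk$|\\.tree$|\\.txt$", ".categories.txt", path))
  invisible(path)
}

#' @param path Newick file with optional `#k` branch tags.
#' @param category_names optional names for the numeric codes (`#0` first).
#' @rdname labeled_tree_io
#' @export
read_labeled_tree <- function(path, category_names = NULL) {
  tr <- ape::read.tree(path)
  ntip <- length(tr$tip.label)
  tipcode <- suppressWarnings(
    as.integer(sub("^.*#(\\d+)$", "\\1", tr$tip.label)))
  tipcode[!grepl("#\\d+$", tr$tip.label)] <- NA
  tr$tip.label <- sub("#\\d+$", "", tr$tip.label)
  nodecode <- rep(NA_integer_, tr$Nnode)
  if (!is.null(tr$node.label)) {
    nodecode <- suppressWarnings(
      as.integer(sub("^.*#(\\d+)$", "\\1", tr$node.label)))
    nodecode[!grepl("#\\d+$", tr$node.label)] <- NA
    tr$node.label <- sub("#\\d+$", "", tr$node.label)
  }
  allcode <- c(tipcode, nodecode)
  code <- allcode[tr$edge[, 2]]
  code[is.na(code)] <- 0L
  if (is.null(category_names)) {
    cats <- paste0("cat", code)
  } else {
    cats <- category_names[code + 1L]
  }
  labeled_tree(tr, cats)
}
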