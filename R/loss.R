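# Aggregation of per-taxon mutations into homologous lesions, Dollo
# placement of lesion origins on the species tree, and counting of
# independent inactivation events.

#' Build a lesion x taxon mutation matrix
#'
#' Lesions are merged across taxa by the identity key (kind,
#' reference-projected coordinate, length); matching requires exact
#' coordinates and lengths unless `coord_tolerance` is raised. Taxa whose
#' coding status is inconclusive are marked unknown (NA) at lesions
#' falling inside their uncovered reference intervals (or at every lesion
#' when no interval information is given).
#'
#' @param per_taxon_mutations named list of mutation tables (one per
#'   taxon), reference-projected against a common reference.
#' @param statuses named character vector of coding statuses
#'   (intact/eroded/inconclusive) per taxon.
#' @param uncovered optional named list of data frames (`start`, `end`,
#'   1-based reference-CDS intervals) of positions a taxon could not be
#'   scored at.
#' @param coord_tolerance merge lesions whose coordinates differ by at most
#'   this many nt (default 0: exact matching).
#' @return a `MutationMatrix`: list with `matrix` (1 present / 0 absent /
#'   NA unknown; lesion rows x taxon columns) and `lesions` (key table).
#' @export
build_mutation_matrix <- function(per_taxon_mutations, statuses,
                                  uncovered = NULL, coord_tolerance = 0L) {
  taxa <- names(statuses)
  stopifnot(!is.null(taxa), all(names(per_taxon_mutations) %in% taxa))

  all_rows <- list()
  for (tx in names(per_taxon_mutations)) {
    m <- per_taxon_mutations[[tx]]
    if (is.null(m) || nrow(m) == 0L) next
    keep <- m$kind %in% c("frameshift_deletion", "frameshift_insertion",
                          "premature_stop", "truncation")
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) next
    all_rows[[tx]] <- data.frame(taxon = tx, kind = m$kind,
                                 ref_coord = m$ref_coord,
                                 length_nt = m$length_nt,
                                 stringsAsFactors = FALSE)
  }
  if (length(all_rows) == 0L) {
    return(structure(list(
      matrix = matrix(0L, 0L, length(taxa),
                      dimnames = list(NULL, taxa)),
      lesions = data.frame(kind = character(0), ref_coord = integer(0),
                           length_nt = integer(0))),
      class = "MutationMatrix"))
  }
  obs <- do.call(rbind, all_rows)

  # cluster observations into lesions by key (optionally with tolerance)
  obs$len_key <- ifelse(is.na(obs$length_nt), -1L, obs$length_nt)
  obs <- obs[order(obs$kind, obs$len_key, obs$ref_coord), , drop = FALSE]
  lesion_id <- integer(nrow(obs))
  lid <- 0L
  for (i in seq_len(nrow(obs))) {
    if (i > 1L && obs$kind[i] == obs$kind[i - 1L] &&
        obs$len_key[i] == obs$len_key[i - 1L] &&
        obs$ref_coord[i] - obs$ref_coord[i - 1L] <= coord_tolerance) {
      lesion_id[i] <- lid
    } else {
      lid <- lid + 1L
      lesion_id[i] <- lid
    }
  }
  obs$lesion <- lesion_id

  groups <- split(obs, obs$lesion)
  groups <- groups[order(as.integer(names(groups)))]
  lesions <- do.call(rbind, lapply(groups, function(g) {
    data.frame(kind = g$kind[1L], ref_coord = min(g$ref_coord),
               length_nt = g$length_nt[1L], stringsAsFactors = FALSE)
  }))
  rownames(lesions) <- NULL

  # identical (coord, length) under different kinds: kept distinct, warn
  key_cl <- paste(lesions$ref_coord, lesions$length_nt)
  dup <- duplicated(key_cl) | duplicated(key_cl, fromLast = TRUE)
  if (any(dup))
    warning("lesions with identical coordinate/length but different ",
            "kinds kept distinct: ",
            paste(unique(key_cl[dup]), collapse = "; "))

  mat <- matrix(0L, nrow(lesions), length(taxa),
                dimnames = list(NULL, taxa))
  for (i in seq_len(nrow(obs)))
    mat[obs$lesion[i], obs$taxon[i]] <- 1L

  # unknowns: inconclusive taxa at positions they could not be scored at
  for (tx in taxa[statuses == "inconclusive"]) {
    iv <- uncovered[[tx]]
    for (r in seq_len(nrow(lesions))) {
      if (mat[r, tx] == 1L) next
      inside <- if (is.null(iv) || nrow(iv) == 0L) TRUE
        else any(lesions$ref_coord[r] >= iv$start &
                   lesions$ref_coord[r] <= iv$end)
      if (inside) mat[r, tx] <- NA
    }
  }
  structure(list(matrix = mat, lesions = lesions),
            class = "MutationMatrix")
}

#' @export
print.MutationMatrix <- function(x, ...) {
  cat("MutationMatrix:", nrow(x$lesions), "lesion(s) x",
      ncol(x$matrix), "taxa\n")
  print(cbind(x$lesions, x$matrix))
  invisible(x)
}

.node_known_leaves <- function(tree, node, known) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    lab <- tree$tip.label[node]
    return(if (lab %in% known) lab else character(0))
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .node_known_leaves, tree = tree, known = known))
}

# Dollo origins of one lesion: stems of the maximal nodes whose known
# descendant leaves are all carriers, jointly covering every carrier. The
# root has no stem branch, so a lesion valid at the root is placed on the
# root's child branches instead (an origin older than the tree cannot be
# dated to a branch).
.lesion_origins <- function(tree, carriers, known) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  origins <- integer(0)
  walk <- function(node) {
    kl <- .node_known_leaves(tree, node, known)
    if (node != root && length(kl) > 0L && all(kl %in% carriers)) {
      origins <<- c(origins, node)
      return(invisible())
    }
    if (node > ntip) {
      for (k in tree$edge[tree$edge[, 1] == node, 2]) walk(k)
    }
  }
  walk(root)
  # keep only origins that actually contain a carrier (pure-unknown
  # subtrees contribute nothing)
  origins[vapply(origins, function(nd) {
    any(.node_known_leaves(tree, nd, known) %in% carriers)
  }, logical(1))]
}

.root_path_edges <- function(tree, tip) {
  path <- integer(0)
  node <- tip
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0L) break
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

.describe_edge <- function(tree, e) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[e, 2]
  if (child <= ntip) return(tree$tip.label[child])
  paste0("stem(", paste(sort(
    tree$tip.label[ape::prop.part(tree)[[child - ntip]]]), collapse = ","),
    ")")
}

#' Count independent gene-loss events under Dollo parsimony
#'
#' Each lesion arises once and is never reverted: it is placed on the stem
#' of the smallest clade containing all of its carriers after setting
#' unknown taxa aside; non-monophyletic carriers split into
#' per-maximal-subclade origins. The inactivation branch of an eroded leaf
#' is the most basal lesion-bearing branch on its root path; the event set
#' is the set of distinct inactivation branches.
#'
#' @param matrix a [build_mutation_matrix()] result.
#' @param tree rooted `phylo` containing every carrier taxon.
#' @return a `LossEventSet`: list with `count`, `branches` (data frame:
#'   edge, child node, description), and `lesion_origins` (list of edge
#'   vectors per lesion).
#' @export
count_independent_losses <- function(matrix, tree) {
  stopifnot(inherits(matrix, "MutationMatrix"), inherits(tree, "phylo"))
  m <- matrix$matrix
  taxa <- colnames(m)
  carriers_all <- taxa[colSums(m == 1L, na.rm = TRUE) > 0L]
  missing <- setdiff(carriers_all, tree$tip.label)
  if (length(missing) > 0L)
    stop("carrier taxa absent from tree: ", paste(missing, collapse = ", "))

  origins <- vector("list", nrow(m))
  lesion_edges <- vector("list", nrow(m))
  for (r in seq_len(nrow(m))) {
    carriers <- taxa[which(m[r, ] == 1L)]
    if (length(carriers) == 0L) next
    known <- taxa[which(!is.na(m[r, ]))]
    known <- intersect(known, tree$tip.label)
    nodes <- .lesion_origins(tree, carriers, known)
    origins[[r]] <- nodes
    lesion_edges[[r]] <- vapply(nodes, function(nd)
      which(tree$edge[, 2] == nd), integer(1))
  }

  all_lesion_edges <- unique(unlist(lesion_edges))
  eroded <- taxa[colSums(m == 1L, na.rm = TRUE) > 0L]
  event_edges <- integer(0)
  for (tx in eroded) {
    tip <- match(tx, tree$tip.label)
    path <- .root_path_edges(tree, tip)   # tip-to-root order
    on_path <- intersect(path, all_lesion_edges)
    if (length(on_path) == 0L) next
    basal <- on_path[which.max(match(on_path, path))]
    event_edges <- c(event_edges, basal)
  }
  event_edges <- sort(unique(event_edges))
  branches <- data.frame(
    edge = event_edges,
    child = tree$edge[event_edges, 2],
    description = vapply(event_edges, .describe_edge, character(1),
                         tree = tree),
    stringsAsFactors = FALSE)
  structure(list(count = length(event_edges), branches = branches,
                 lesion_origins = lesion_edges, tree = tree),
            class = "LossEventSet")
}

#' @export
print.LossEventSet <- function(x, ...) {
  cat("LossEventSet:", x$count, "independent inactivation event(s)\n")
  if (x$count > 0L)
    cat(paste0("  - ", x$branches$description, collapse = "\n"), "\n")
  invisible(x)
}
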