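# Lesion aggregation, Dollo event counting and branch-category labeling.

cet_tree <- ape::read.tree(text = geneloss:::.cetacea_newick)
odont_no_sperm <- c("yangtze_river_dolphin", "finless_porpoise",
                    "beluga_whale", "killer_whale", "white_sided_dolphin",
                    "bottlenose_dolphin", "humpback_dolphin")
myst_carriers <- c("bowhead_whale", "gray_whale", "antarctic_minke_whale")

cetacean_matrix <- function() {
  muts <- list()
  for (tx in odont_no_sperm)
    muts[[tx]] <- data.frame(kind = "frameshift_deletion",
                             ref_coord = 517L, length_nt = 2L)
  muts$sperm_whale <- data.frame(
    kind = c("premature_stop", "frameshift_insertion"),
    ref_coord = c(721L, 1333L), length_nt = c(NA, 1L))
  for (tx in myst_carriers)
    muts[[tx]] <- data.frame(kind = "frameshift_deletion",
                             ref_coord = 145L, length_nt = 1L)
  statuses <- stats::setNames(rep("intact", length(cet_tree$tip.label)),
                              cet_tree$tip.label)
  statuses[names(muts)] <- "eroded"
  statuses["minke_whale"] <- "inconclusive"
  build_mutation_matrix(
    muts, statuses,
    uncovered = list(minke_whale = data.frame(start = 1L, end = 450L)))
}

test_that("identical lesion keys merge across taxa; unknowns are scoped", {
  mm <- cetacean_matrix()
  expect_equal(nrow(mm$lesions), 4L)
  shared2 <- which(mm$lesions$ref_coord == 517L)
  expect_equal(sum(mm$matrix[shared2, ] == 1L, na.rm = TRUE), 7L)
  # the minke whale is unknown at the 5' lesion but scored absent at the
  # others (outside its uncovered interval)
  myst1 <- which(mm$lesions$ref_coord == 145L)
  expect_true(is.na(mm$matrix[myst1, "minke_whale"]))
  expect_equal(mm$matrix[shared2, "minke_whale"], 0L, ignore_attr = TRUE)
})

test_that("conflicting kinds at one coordinate stay distinct with warning", {
  muts <- list(t1 = data.frame(kind = "premature_stop", ref_coord = 99L,
                               length_nt = NA_integer_),
               t2 = data.frame(kind = "truncation", ref_coord = 99L,
                               length_nt = NA_integer_))
  expect_warning(
    mm <- build_mutation_matrix(muts, c(t1 = "eroded", t2 = "eroded")),
    "distinct")
  expect_equal(nrow(mm$lesions), 2L)
})

test_that("the cetacean pattern yields exactly three independent events", {
  mm <- cetacean_matrix()
  ev <- count_independent_losses(mm, cet_tree)
  expect_equal(ev$count, 3L)
  desc <- ev$branches$description
  expect_true(any(desc == "sperm_whale"))
  myst_stem <- paste0("stem(", paste(sort(c(myst_carriers, "minke_whale")),
                                     collapse = ","), ")")
  expect_true(myst_stem %in% desc)
  odont_stem <- paste0("stem(", paste(sort(odont_no_sperm),
                                      collapse = ","), ")")
  expect_true(odont_stem %in% desc)
})

test_that("a private lesion maps to the terminal branch", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  muts <- list(a = data.frame(kind = "premature_stop", ref_coord = 10L,
                              length_nt = NA_integer_))
  mm <- build_mutation_matrix(muts, c(a = "eroded", b = "intact",
                                      c = "intact", d = "intact"))
  ev <- count_independent_losses(mm, tr)
  expect_equal(ev$count, 1L)
  expect_equal(ev$branches$description, "a")
  expect_error(count_independent_losses(
    mm, ape::drop.tip(tr, "a")), "absent from tree")
})

test_that("event counts match the exhaustive Dollo oracle", {
  set.seed(61)
  for (rep in 1:30) {
    ntip <- sample(4:6, 1)
    tr <- ape::rtree(ntip)
    tr$tip.label <- paste0("t", seq_len(ntip))
    nles <- sample(1:3, 1)
    mat <- matrix(sample(c(1L, 0L, 0L, NA), nles * ntip, replace = TRUE),
                  nles, ntip, dimnames = list(NULL, tr$tip.label))
    if (all(colSums(mat == 1L, na.rm = TRUE) == 0)) next
    mm <- structure(list(
      matrix = mat,
      lesions = data.frame(kind = rep("premature_stop", nles),
                           ref_coord = seq_len(nles) * 10L,
                           length_nt = NA_integer_)),
      class = "MutationMatrix")
    ev <- count_independent_losses(mm, tr)
    expect_equal(ev$count, dollo_oracle_count(mat, tr),
                 info = paste("rep", rep))
  }
})

test_that("event bounds and unknown-monotonicity hold", {
  set.seed(62)
  for (rep in 1:15) {
    tr <- ape::rtree(6)
    tr$tip.label <- paste0("t", 1:6)
    mat <- matrix(sample(c(1L, 0L), 12, replace = TRUE), 2, 6,
                  dimnames = list(NULL, tr$tip.label))
    if (all(mat != 1L)) next
    mm <- structure(list(matrix = mat, lesions = data.frame(
      kind = c("premature_stop", "frameshift_deletion"),
      ref_coord = c(10L, 20L), length_nt = c(NA, 1L))),
      class = "MutationMatrix")
    ev <- count_independent_losses(mm, tr)
    n_eroded <- sum(colSums(mat == 1L) > 0)
    expect_gte(ev$count, 1L)
    expect_lte(ev$count, n_eroded)
    # marking one absent taxon unknown never increases the count
    zeros <- which(colSums(mat == 1L) == 0)
    if (length(zeros) > 0) {
      mat2 <- mat
      mat2[, zeros[1]] <- NA
      mm2 <- mm
      mm2$matrix <- mat2
      expect_lte(count_independent_losses(mm2, tr)$count, ev$count)
    }
  }
})

test_that("the seven-category scheme labels every branch exactly once", {
  g <- geneloss:::.cetacea_groups
  sch <- cetacean_scheme(g$mysticeti, g$odontoceti, g$sperm_whale)
  lt <- label_branch_categories(cet_tree, sch)
  tab <- table(lt$categories)
  expect_equal(length(tab), 7L)
  expect_true(all(tab >= 1L))
  expect_equal(sum(tab), nrow(cet_tree$edge))
  expect_equal(unname(tab["cetacea_stem"]), 1L)
  expect_equal(unname(tab["sperm_whale_ancestor"]), 1L)

  # one-category scheme: the one-ratio model
  lt1 <- label_branch_categories(cet_tree, list(all = sel_rest()))
  expect_equal(unique(lt1$categories), "all")

  expect_error(label_branch_categories(
    cet_tree, list(functional = sel_rest(),
                   ghost = sel_tips("no_such_taxon"))), "unknown tips")
})

test_that("category labels survive Newick rotation and #k round-trips", {
  g <- geneloss:::.cetacea_groups
  sch <- cetacean_scheme(g$mysticeti, g$odontoceti, g$sperm_whale)
  lt <- label_branch_categories(cet_tree, sch)
  rot <- ape::rotateConstr(cet_tree, rev(cet_tree$tip.label))
  lt_rot <- label_branch_categories(rot, sch)
  cat_of_tip <- function(l) {
    tipedges <- match(seq_along(l$tree$tip.label), l$tree$edge[, 2])
    stats::setNames(l$categories[tipedges], l$tree$tip.label)
  }
  c1 <- cat_of_tip(lt)
  expect_equal(c1[sort(names(c1))], cat_of_tip(lt_rot)[sort(names(c1))])

  # codeml-style #k tags round-trip through Newick
  path <- tempfile(fileext = ".nwk")
  write_labeled_tree(lt, path)
  back <- read_labeled_tree(path, category_names = unique(lt$categories))
  c2 <- cat_of_tip(back)
  expect_equal(c1[sort(names(c1))], c2[sort(names(c1))])
})
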