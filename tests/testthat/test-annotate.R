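# Reference-guided mapping, mutation calling, truncation detection and
# coding-status classification.

ref <- make_test_reference(n_codons = 200, seed = 101)
cds_wild <- ref$cds

make_region <- function(cds, seed = 500, n_runs = NULL,
                        fragment_cds = FALSE, strand = "+") {
  set.seed(seed)
  flanks <- list(upstream = c(u = random_dna_str(300)),
                 downstream = c(d = random_dna_str(300)))
  build_locus(paste0(ref$utr5, cds, ref$utr3), flanks,
              intergenic_length = 150, n_runs = n_runs,
              fragment_cds = fragment_cds, strand = strand,
              seed = seed)$locus
}

test_that("an exact region maps with full coverage and no calls", {
  region <- make_region(cds_wild)
  aln <- map_reference_cds(ref, region)
  expect_equal(aln$coverage, 1)
  expect_equal(aln$unambiguous_coverage, 1)
  expect_equal(aln$strand, "+")
  expect_equal(nrow(call_inactivating_mutations(aln)), 0L)
  expect_equal(classify_coding_status(
    call_inactivating_mutations(aln), aln), "intact")
})

test_that("strand selection reproduces the same alignment", {
  les <- inject_lesions(cds_wild, list(lesion_spec("deletion", 0.3, 2L)),
                        seed = 1)
  fwd <- map_reference_cds(ref, make_region(les$seq))
  rev <- map_reference_cds(ref, make_region(les$seq, strand = "-"))
  expect_equal(rev$strand, "-")
  m1 <- call_inactivating_mutations(fwd)
  m2 <- call_inactivating_mutations(rev)
  expect_equal(m1[, c("kind", "ref_coord", "length_nt")],
               m2[, c("kind", "ref_coord", "length_nt")])
})

test_that("a 2-nt deletion shows as a reference-side bulge at the truth", {
  les <- inject_lesions(cds_wild, list(lesion_spec("deletion", 0.4, 2L)),
                        seed = 2)
  aln <- map_reference_cds(ref, make_region(les$seq))
  m <- call_inactivating_mutations(aln)
  fs <- m[m$kind == "frameshift_deletion", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$ref_coord, les$truth$ref_coord)
  expect_equal(fs$length_nt, 2L)
})

test_that("no-ortholog regions are rejected", {
  set.seed(3)
  expect_error(map_reference_cds(ref, random_dna_str(3000)),
               "no ortholog")
})

test_that("frameshifts, stops and compensation are called together", {
  les <- inject_lesions(
    cds_wild,
    list(lesion_spec("deletion", 0.2, 1L), lesion_spec("insertion", 0.5, 1L),
         lesion_spec("nonsense", 0.75)), seed = 4)
  aln <- map_reference_cds(ref, make_region(les$seq))
  m <- call_inactivating_mutations(aln)
  for (i in seq_len(nrow(les$truth))) {
    t <- les$truth[i, ]
    hit <- m[m$kind == t$kind & m$ref_coord == t$ref_coord, ]
    expect_gte(nrow(hit), 1L)
    if (!is.na(t$length_nt)) expect_equal(hit$length_nt[1], t$length_nt)
  }
  # deletion + insertion restore the net frame: both flagged compensated
  fs <- m[grepl("frameshift", m$kind), ]
  expect_true(all(fs$compensated))
})

test_that("premature stops are invariant to the supplied UTR lengths", {
  les <- inject_lesions(cds_wild, list(lesion_spec("nonsense", 0.5)),
                        seed = 5)
  region <- make_region(les$seq)
  bare <- reference_gene(ref$cds)
  m1 <- call_inactivating_mutations(map_reference_cds(ref, region))
  m2 <- call_inactivating_mutations(map_reference_cds(bare, region))
  s1 <- m1[m1$kind == "premature_stop", c("ref_coord", "codon_index")]
  s2 <- m2[m2$kind == "premature_stop", c("ref_coord", "codon_index")]
  expect_equal(s1, s2)
})

test_that("a stop in the terminal codon is never premature", {
  aln <- map_reference_cds(ref, make_region(cds_wild))
  m <- call_inactivating_mutations(aln)
  expect_false(any(m$kind == "premature_stop"))
})

test_that("frame bookkeeping: removing frameshift columns restores frame", {
  les <- inject_lesions(
    cds_wild, list(lesion_spec("deletion", 0.25, 2L),
                   lesion_spec("insertion", 0.6, 1L)), seed = 6)
  aln <- map_reference_cds(ref, make_region(les$seq))
  fc <- frame_corrected_cds(aln)
  expect_equal(nchar(fc), nchar(ref$cds))
  # frame-corrected sequence differs from the wild CDS only at lesion
  # positions (deleted bases become ?)
  w <- strsplit(cds_wild, "")[[1]]
  f <- strsplit(fc, "")[[1]]
  mism <- which(w != f)
  expect_true(all(f[mism] == "?"))
  expect_equal(length(mism), 2L)
})

test_that("truncation detection finds an abrupt identity drop", {
  aln_clean <- map_reference_cds(ref, make_region(cds_wild))
  expect_null(detect_truncation(aln_clean))

  set.seed(7)
  cut <- floor(nchar(cds_wild) * 0.5)
  broken <- paste0(substr(cds_wild, 1, cut),
                   random_dna_str(nchar(cds_wild) - cut))
  aln_tr <- map_reference_cds(ref, make_region(broken))
  tr <- detect_truncation(aln_tr)
  expect_false(is.null(tr))
  expect_false(tr$inconclusive)
  junction_ref <- nchar(ref$utr5) + cut
  expect_lt(abs(tr$breakpoint - junction_ref), 60)

  # all-N second half: inconclusive, not a truncation
  masked <- paste0(substr(cds_wild, 1, cut),
                   paste(rep("N", nchar(cds_wild) - cut), collapse = ""))
  aln_n <- map_reference_cds(ref, make_region(masked))
  trn <- detect_truncation(aln_n)
  expect_true(trn$inconclusive)
  expect_true(is.na(trn$breakpoint))
})

test_that("coding status follows coverage then mutations, monotonically", {
  region <- make_region(cds_wild)
  aln <- map_reference_cds(ref, region)
  expect_equal(classify_coding_status(NULL, aln), "intact")

  one_fs <- data.frame(kind = "frameshift_deletion", ref_coord = 10L)
  expect_equal(classify_coding_status(one_fs, aln), "eroded")

  # masking the 5' fifth of the gene makes the taxon unscorable
  cut <- floor(nchar(cds_wild) * 0.2)
  masked <- paste0(paste(rep("N", cut), collapse = ""),
                   substring(cds_wild, cut + 1))
  aln_m <- map_reference_cds(ref, make_region(masked))
  expect_lt(aln_m$unambiguous_coverage, 0.9)
  m <- call_inactivating_mutations(aln_m)
  expect_equal(classify_coding_status(m, aln_m), "inconclusive")

  # monotone: adding mutations never moves eroded back to intact
  expect_equal(classify_coding_status(rbind(one_fs, one_fs), aln), "eroded")
})

test_that("N runs never produce stop or indel calls", {
  cut <- floor(nchar(cds_wild) * 0.3)
  masked <- paste0(substr(cds_wild, 1, cut),
                   paste(rep("N", 60), collapse = ""),
                   substring(cds_wild, cut + 61))
  aln <- map_reference_cds(ref, make_region(masked))
  m <- call_inactivating_mutations(aln)
  expect_equal(nrow(m), 0L)
})
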