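# Read-based validation of called mutations.

ref_v <- make_test_reference(n_codons = 200, seed = 201)

make_validation_fixture <- function(lesion, seed) {
  cds <- ref_v$cds
  inj <- inject_lesions(cds, list(lesion), seed = seed)
  set.seed(seed)
  flanks <- list(upstream = c(u = random_dna_str(250)),
                 downstream = c(d = random_dna_str(250)))
  mut <- build_locus(paste0(ref_v$utr5, inj$seq, ref_v$utr3), flanks,
                     seed = seed)$locus
  wild <- build_locus(paste0(ref_v$utr5, cds, ref_v$utr3), flanks,
                      seed = seed)$locus
  aln <- map_reference_cds(ref_v, mut)
  muts <- call_inactivating_mutations(aln)
  list(aln = aln, mutation = muts[1, ], mut = mut, wild = wild)
}

test_that("mutant-only reads confirm, wild-only reads refute", {
  fx <- make_validation_fixture(lesion_spec("nonsense", 0.5), 301)
  rm_ <- simulate_reads(fx$mut, depth = 20, read_len = 100, error_rate = 0,
                        seed = 1)
  v <- validate_mutation(fx$mutation, fx$aln, rm_$reads)
  expect_equal(v$verdict, "confirmed")
  expect_equal(v$support_fraction, 1)

  rw <- simulate_reads(fx$wild, depth = 20, read_len = 100, error_rate = 0,
                       seed = 2)
  v2 <- validate_mutation(fx$mutation, fx$aln, rw$reads)
  expect_equal(v2$verdict, "refuted")
  expect_equal(v2$support_fraction, 0)
})

test_that("indel mutations are validated too", {
  for (les in list(lesion_spec("deletion", 0.45, 2L),
                   lesion_spec("insertion", 0.6, 1L))) {
    fx <- make_validation_fixture(les, 302)
    rm_ <- simulate_reads(fx$mut, depth = 20, read_len = 100,
                          error_rate = 0, seed = 3)
    expect_equal(validate_mutation(fx$mutation, fx$aln, rm_$reads)$verdict,
                 "confirmed")
    rw <- simulate_reads(fx$wild, depth = 20, read_len = 100,
                         error_rate = 0, seed = 4)
    expect_equal(validate_mutation(fx$mutation, fx$aln, rw$reads)$verdict,
                 "refuted")
  }
})

test_that("a 50/50 allele mixture is called polymorphic", {
  fx <- make_validation_fixture(lesion_spec("nonsense", 0.5), 303)
  mix <- simulate_reads(fx$mut, depth = 50, read_len = 250, error_rate = 0,
                        allele_mix = c(m = 0.5, w = 0.5),
                        alleles = c(m = fx$mut$seq, w = fx$wild$seq),
                        seed = 5)
  v <- validate_mutation(fx$mutation, fx$aln, mix$reads, flank_nt = 20)
  expect_equal(v$verdict, "polymorphic")
  expect_gt(v$support_fraction, 0.35)
  expect_lt(v$support_fraction, 0.65)
})

test_that("verdicts are invariant to read order and orientation", {
  fx <- make_validation_fixture(lesion_spec("deletion", 0.5, 2L), 304)
  rm_ <- simulate_reads(fx$mut, depth = 12, read_len = 100, error_rate = 0,
                        seed = 6)
  v1 <- validate_mutation(fx$mutation, fx$aln, rm_$reads)
  set.seed(7)
  shuffled <- sample(rm_$reads)
  v2 <- validate_mutation(fx$mutation, fx$aln, shuffled)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rm_$reads)))
  v3 <- validate_mutation(fx$mutation, fx$aln, rc)
  expect_equal(v1$support_fraction, v2$support_fraction)
  expect_equal(v1$n_support, v3$n_support)
  expect_equal(v1$verdict, v3$verdict)
})

test_that("too few informative reads give no_data; errors are raised", {
  fx <- make_validation_fixture(lesion_spec("nonsense", 0.5), 305)
  v <- validate_mutation(fx$mutation, fx$aln, character(0))
  expect_equal(v$verdict, "no_data")
  # reads that do not overlap the site are uninformative
  far <- substr(fx$mut$seq, 1, 100)
  v2 <- validate_mutation(fx$mutation, fx$aln, c(r1 = far, r2 = far))
  expect_equal(v2$verdict, "no_data")
  bad <- fx$mutation
  bad$region_coord <- nchar(fx$mut$seq) + 100L
  expect_error(validate_mutation(bad, fx$aln, c(r1 = far)),
               "outside region")
})

test_that("multi-set consensus distinguishes agreement from conflict", {
  fx <- make_validation_fixture(lesion_spec("nonsense", 0.5), 306)
  rm1 <- simulate_reads(fx$mut, depth = 15, read_len = 100,
                        error_rate = 0, seed = 8)$reads
  rm2 <- simulate_reads(fx$mut, depth = 15, read_len = 100,
                        error_rate = 0, seed = 9)$reads
  rw <- simulate_reads(fx$wild, depth = 15, read_len = 100,
                       error_rate = 0, seed = 10)$reads
  both <- validate_all(fx$mutation, fx$aln,
                       list(sra1 = rm1, sra2 = rm2))
  expect_true(all(both$consensus == "confirmed"))
  conflict <- validate_all(fx$mutation, fx$aln,
                           list(sra1 = rm1, sra2 = rw))
  expect_true(all(conflict$consensus == "polymorphic_or_conflict"))
  hetero <- validate_all(fx$mutation, fx$aln, list(
    sra1 = c(rm1[1:20], rw[1:20])))
  expect_true(all(hetero$consensus %in%
                    c("polymorphic_or_conflict", "no_data")))
})
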