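# The synthetic-locus generator: sequence evolution, lesion injection,
# locus assembly and read simulation.

test_that("zero-length branches copy the root sequence to every leaf", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  root <- geneloss:::random_root_cds(50, 1)
  spec <- evolution_spec(tr, 0.5, kappa = 2, root_cds = root, seed = 2)
  sim <- simulate_cds_evolution(spec)
  expect_true(all(sim$cds == root))
})

test_that("simulation is deterministic given the seed and rejects stops", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  root <- geneloss:::random_root_cds(60, 3)
  spec <- evolution_spec(tr, 1, kappa = 2, root_cds = root, seed = 4)
  s1 <- simulate_cds_evolution(spec)
  s2 <- simulate_cds_evolution(spec)
  expect_identical(s1$cds, s2$cds)
  expect_false(any(vapply(s1$cds, function(s)
    any(geneloss:::.split_codons(s) %in% c("TAA", "TAG", "TGA")),
    logical(1))))
  expect_error(evolution_spec(tr, 1, kappa = 2,
                              root_cds = paste0("ATGTAA", root),
                              seed = 1),
               "stop codon")
})

test_that("substitution partition matches the generator matrix", {
  # two leaves, one long branch: the observed fraction of nonsynonymous
  # codon changes should match the conditional substitution partition of
  # P(t), computed by brute force from the generator
  tr <- ape::read.tree(text = "(a:0,b:10);")
  pi <- rep(1 / 61, 61)
  root <- geneloss:::random_root_cds(500, 5)
  spec <- evolution_spec(tr, 1, kappa = 2, root_cds = root, seed = 6,
                         codon_freqs = pi)
  sim <- simulate_cds_evolution(spec)
  a <- geneloss:::.split_codons(sim$cds[["a"]])
  b <- geneloss:::.split_codons(sim$cds[["b"]])
  changed <- a != b
  aa_a <- translate_codons(a)
  aa_b <- translate_codons(b)
  obs_nonsyn <- sum(changed & aa_a != aa_b)

  Q <- gy94_rate_matrix(2, 1, pi)
  P <- gy94_transition_matrix(Q, 10, pi)
  aa <- translate_codons(sense_codons())
  nonsyn <- outer(aa, aa, "!=")
  offdiag <- !diag(61)
  # expected counts conditional on the realized start codons of 'a'
  st <- match(a, sense_codons())
  p_ns <- vapply(st, function(i) sum(P[i, nonsyn[i, ] & offdiag[i, ]]),
                 numeric(1))
  p_ch <- vapply(st, function(i) sum(P[i, offdiag[i, ]]), numeric(1))
  expect_equal(sum(changed), sum(p_ch), tolerance = 3 *
                 sqrt(sum(p_ch * (1 - p_ch))) / sum(p_ch))
  se <- sqrt(sum(p_ns * (1 - p_ns)))
  expect_lt(abs(obs_nonsyn - sum(p_ns)), 4 * se)
})

test_that("lesion injection does exact coordinate bookkeeping", {
  cds <- geneloss:::random_root_cds(100, 7)

  expect_identical(inject_lesions(cds, list())$seq, cds)

  one <- inject_lesions(cds, list(lesion_spec("deletion", 0.4, 2L)),
                        seed = 1)
  expect_equal(nchar(one$seq), nchar(cds) - 2L)
  expect_equal(one$truth$kind, "frameshift_deletion")
  s <- one$truth$ref_coord
  expect_identical(paste0(substr(cds, 1, s - 1), substring(cds, s + 2)),
                   one$seq)

  ins <- inject_lesions(cds, list(lesion_spec("insertion", 0.5, 1L)),
                        seed = 2)
  expect_equal(nchar(ins$seq), nchar(cds) + 1L)
  expect_identical(substr(ins$seq, ins$truth$mut_coord,
                          ins$truth$mut_coord), ins$truth$inserted)

  expect_error(
    inject_lesions(cds, list(lesion_spec("deletion", 0.5, 2L),
                             lesion_spec("deletion", 0.5, 2L)), seed = 1),
    "overlap")
})

test_that("nonsense injection picks the nearest stop, ties to TAA", {
  # craft codons at known positions: TCA -> TAA or TGA are both 1 change;
  # tie resolves to TAA
  cds <- paste0("ATGGCT", "TCA", "GCTGCTGGA")
  out <- inject_lesions(cds, list(lesion_spec("nonsense", 2 / 6)), seed = 1)
  expect_equal(substr(out$seq, 7, 9), "TAA")
  # TGG (Trp) is 1 change from TGA and TAG, 2 from TAA: picks TAG? No --
  # TGA and TAG are both distance 1; tie order is TAA, TAG, TGA: TAG wins
  cds2 <- paste0("ATGGCT", "TGG", "GCTGCTGGA")
  out2 <- inject_lesions(cds2, list(lesion_spec("nonsense", 2 / 6)),
                         seed = 1)
  expect_equal(substr(out2$seq, 7, 9), "TAG")
  expect_equal(out2$truth$kind, "premature_stop")
  expect_equal(out2$truth$codon_index, 3L)
})

test_that("the odontoceti-like lesion pattern is reproduced", {
  # shared 2-nt deletion on a stem; the sperm-whale-like taxon instead has
  # a mid-gene premature stop and a 1-nt insertion near the end
  cds <- paste0(geneloss:::random_root_cds(200, 9), "TAA")
  shared <- lesion_spec("deletion", 0.35, 2L)
  sperm <- list(lesion_spec("nonsense", 0.5),
                lesion_spec("insertion", 0.92, 1L))
  d1 <- inject_lesions(cds, list(shared), seed = 1)
  d2 <- inject_lesions(cds, list(shared), seed = 2)
  expect_equal(d1$truth$ref_coord, d2$truth$ref_coord)  # same lesion
  ds <- inject_lesions(cds, sperm, seed = 3)
  expect_setequal(ds$truth$kind, c("premature_stop",
                                   "frameshift_insertion"))
  ncod <- nchar(cds) / 3
  stop_frac <- ds$truth$codon_index[ds$truth$kind == "premature_stop"] / ncod
  expect_gt(stop_frac, 0.4)
  expect_lt(stop_frac, 0.6)
  expect_gt(max(ds$truth$ref_coord) / nchar(cds), 0.85)
})

test_that("build_locus places the CDS and handles strand and N runs", {
  cds <- geneloss:::random_root_cds(50, 11)
  plain <- build_locus(cds, list(), seed = 1)
  expect_identical(plain$locus$seq, cds)
  expect_equal(plain$locus$cds_interval, c(1L, nchar(cds)))

  flanks <- list(upstream = c(u1 = random_dna_str(100)),
                 downstream = c(d1 = random_dna_str(100)))
  fwd <- build_locus(cds, flanks, intergenic_length = 50, seed = 2)
  iv <- fwd$locus$cds_interval
  expect_identical(substr(fwd$locus$seq, iv[1], iv[2]), cds)

  rev <- build_locus(cds, flanks, intergenic_length = 50, strand = "-",
                     seed = 2)
  expect_identical(rev$locus$seq,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(fwd$locus$seq))))

  expect_error(build_locus(cds, flanks, n_runs = data.frame(
    at = 0.1, length = 30, relative_to = "cds"), seed = 2),
    "N run overlaps")
  masked <- build_locus(cds, flanks, n_runs = data.frame(
    at = 0.1, length = 30, relative_to = "cds"), fragment_cds = TRUE,
    seed = 2)
  expect_equal(nrow(masked$locus$n_runs), 1L)
  expect_true(grepl("N{30}", masked$locus$seq))
})

test_that("read simulation respects depth, errors and the allele mix", {
  locus <- random_dna_str(2000)
  rs <- simulate_reads(locus, depth = 30, read_len = 100, error_rate = 0,
                       seed = 1)
  expect_equal(length(rs$reads), 600L)
  # every read (or its reverse complement) is an exact substring
  hits <- vapply(seq_along(rs$reads), function(i) {
    r <- rs$reads[[i]]
    grepl(r, locus, fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r))), locus, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  # mean per-base coverage within 3 Poisson SDs of the target depth
  cov <- sum(nchar(rs$reads)) / nchar(locus)
  expect_lt(abs(cov - 30), 3 * sqrt(30))

  expect_error(simulate_reads(locus, depth = 10, read_len = 5000, seed = 1),
               "read_len")

  a2 <- chartr("ACGT", "TGCA", locus)
  mix <- simulate_reads(locus, depth = 20, read_len = 100, error_rate = 0,
                        allele_mix = c(x = 0.5, y = 0.5),
                        alleles = c(x = locus, y = a2), seed = 3)
  expect_equal(unname(table(mix$truth$allele)["x"]),
               unname(table(mix$truth$allele)["y"]))

  err <- simulate_reads(locus, depth = 20, read_len = 100,
                        error_rate = 0.05, seed = 4)
  mism <- mapply(function(r, st, strand) {
    if (strand == "-") r <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r)))
    sum(strsplit(r, "")[[1]] !=
          strsplit(substr(locus, st, st + 99), "")[[1]])
  }, err$reads, err$truth$start, err$truth$strand)
  rate <- sum(mism) / sum(nchar(err$reads))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
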