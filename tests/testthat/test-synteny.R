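# Synteny mapping: best hits, neighbor maps, anchor-based region
# extraction.

test_that("an exact substring is a perfect hit with correct coordinates", {
  set.seed(31)
  q <- random_dna_str(200)
  contig <- paste0(random_dna_str(400), q, random_dna_str(300))
  h <- best_hit(q, c(c1 = contig))
  expect_equal(h$percent_identity, 100)
  expect_equal(h$query_coverage, 100)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 400L)     # 0-based half-open
  expect_equal(h$end, 600L)
  expect_identical(substr(contig, h$start + 1, h$end), q)
})

test_that("reverse-complement copies hit with the strand flipped", {
  set.seed(32)
  q <- random_dna_str(150)
  contig <- paste0(random_dna_str(200), q, random_dna_str(100))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  h <- best_hit(q, c(c1 = contig))
  hr <- best_hit(q, c(c1 = rc))
  expect_equal(hr$strand, "-")
  expect_equal(hr$percent_identity, h$percent_identity)
  expect_equal(hr$end - hr$start, h$end - h$start)
  expect_equal(hr$start, nchar(contig) - h$end)
})

test_that("coverage outranks identity; ranking is input-order invariant", {
  set.seed(33)
  q <- random_dna_str(300)
  # full-length copy at 95% identity
  full <- strsplit(q, "")[[1]]
  mut <- sample(300, 15)
  full[mut] <- vapply(full[mut], function(b) sample(setdiff(NUCS, b), 1),
                      character(1))
  full_copy <- paste0(random_dna_str(100), paste(full, collapse = ""),
                      random_dna_str(100))
  # exact half-length copy
  half_copy <- paste0(random_dna_str(100), substr(q, 1, 150),
                      random_dna_str(100))
  h1 <- best_hit(q, c(full = full_copy, half = half_copy),
                 min_coverage = 30)
  h2 <- best_hit(q, c(half = half_copy, full = full_copy),
                 min_coverage = 30)
  expect_equal(h1$target_contig, "full")
  expect_equal(h2$target_contig, "full")
  expect_equal(h1, h2)
  expect_error(best_hit(q, character(0)), "empty contig set")
  expect_null(best_hit(q, c(x = random_dna_str(500))))
})

test_that("synteny maps preserve construction order and flag the focal gene", {
  set.seed(34)
  genes <- stats::setNames(replicate(5, random_dna_str(250)),
                           paste0("g", 1:5))
  focal <- random_dna_str(400)
  spacer <- function() random_dna_str(120)
  with_focal <- paste0(genes[1], spacer(), genes[2], spacer(), focal,
                       spacer(), genes[3], spacer(), genes[4], spacer(),
                       genes[5])
  without_focal <- paste0(genes[1], spacer(), genes[2], spacer(),
                          spacer(), genes[3], spacer(), genes[4], spacer(),
                          genes[5])
  m1 <- build_synteny_map(genes, c(scaf = with_focal), focal_gene = focal)
  expect_true(m1$focal_present)
  expect_equal(m1$hits$query_gene, paste0("g", 1:5))
  m2 <- build_synteny_map(genes, c(scaf = without_focal),
                          focal_gene = focal)
  expect_false(m2$focal_present)
  expect_equal(sum(!is.na(m2$hits$target_contig)), 5L)
  m3 <- build_synteny_map(genes, c(scaf = "ACGT"))
  expect_true(all(is.na(m3$hits$target_contig)))
})

test_that("the inter-anchor region contains the focal CDS", {
  set.seed(35)
  ok <- 0L
  for (i in 1:20) {
    up <- random_dna_str(300)
    down <- random_dna_str(300)
    cds <- geneloss:::random_root_cds(80, 1000 + i)
    contig <- paste0(random_dna_str(200), up, random_dna_str(150), cds,
                     random_dna_str(150), down, random_dna_str(200))
    hu <- best_hit(up, c(c1 = contig), query_name = "up")
    hd <- best_hit(down, c(c1 = contig), query_name = "down")
    region <- locate_target_region(hu, hd, c(c1 = contig),
                                   padding_nt = 50)
    ok <- ok + grepl(cds, region$seq, fixed = TRUE)
  }
  expect_equal(ok, 20L)
})

test_that("degenerate anchor geometries are reported", {
  set.seed(36)
  a <- random_dna_str(200)
  b <- random_dna_str(200)
  contig <- paste0(a, b)
  ha <- best_hit(a, c(c1 = contig))
  hb <- best_hit(b, c(c1 = contig))
  expect_error(locate_target_region(ha, hb, c(c1 = contig),
                                    padding_nt = 0),
               "empty inter-anchor")

  two <- c(c1 = paste0(a, random_dna_str(100)),
           c2 = paste0(random_dna_str(100), b))
  h1 <- best_hit(a, two["c1"])
  h2 <- best_hit(b, two["c2"])
  expect_error(locate_target_region(h1, h2, two), class =
                 "synteny_unresolved")

  rc_b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  contig2 <- paste0(a, random_dna_str(400), rc_b)
  hu <- best_hit(a, c(c1 = contig2))
  hv <- best_hit(b, c(c1 = contig2))
  expect_warning(locate_target_region(hu, hv, c(c1 = contig2)),
                 "opposite strands")
})
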