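# Bundled deterministic fixtures. Each fixture writes a self-contained run
# directory (reference, loci, tree, reads, truth, config) whose statistical
# structure mirrors the situations the pipeline is built for: a
# cetacean-like radiation with three independent inactivation events, a
# polymorphic (segregating) loss, a locus truncation, and a clean set.

# moderately GC-biased positional nucleotide frequencies used by all
# fixtures; F3x4-composed codon frequencies
.fixture_pos_freqs <- matrix(
  c(0.27, 0.21, 0.31, 0.21,
    0.30, 0.24, 0.19, 0.27,
    0.22, 0.27, 0.27, 0.24),
  nrow = 3, byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T")))

fixture_codon_freqs <- function() {
  fr <- .fixture_pos_freqs
  pi <- fr[1L, substring(.codons, 1L, 1L)] *
    fr[2L, substring(.codons, 2L, 2L)] *
    fr[3L, substring(.codons, 3L, 3L)]
  pi <- pi / sum(pi)
  names(pi) <- .codons
  pi
}

random_root_cds <- function(n_codons, seed, codon_freqs = NULL) {
  if (is.null(codon_freqs)) codon_freqs <- fixture_codon_freqs()
  with_seed(seed, paste(sample(.codons, n_codons, replace = TRUE,
                               prob = codon_freqs), collapse = ""))
}

.cetacea_newick <- paste0(
  "(human:0.11,(cattle:0.09,(hippopotamus:0.08,",
  "((bowhead_whale:0.040,(gray_whale:0.030,(antarctic_minke_whale:0.020,",
  "minke_whale:0.020)balaenoptera:0.015)balaenopteroidea:0.012)",
  "mysticeti:0.035,",
  "(sperm_whale:0.055,(yangtze_river_dolphin:0.045,((finless_porpoise:0.025,",
  "beluga_whale:0.025)phocoenoidea:0.015,(killer_whale:0.018,",
  "(white_sided_dolphin:0.015,(bottlenose_dolphin:0.012,",
  "humpback_dolphin:0.012)tursiops_sousa:0.006)delphininae:0.006)",
  "delphinidae:0.015)delphinoidea:0.012)odontoceti_crown:0.010)",
  "odontoceti:0.028)cetacea:0.060)whippomorpha:0.020)cetruminantia:0.030);")

.cetacea_groups <- list(
  mysticeti = c("bowhead_whale", "gray_whale", "antarctic_minke_whale",
                "minke_whale"),
  odontoceti = c("sperm_whale", "yangtze_river_dolphin", "finless_porpoise",
                 "beluga_whale", "killer_whale", "white_sided_dolphin",
                 "bottlenose_dolphin", "humpback_dolphin"),
  sperm_whale = "sperm_whale",
  outgroups = c("human", "cattle", "hippopotamus"))

#' Seven-category cetacean branch scheme
#'
#' The partition used for the selection analysis: functional background
#' (outgroups and backbone), common cetacean stem, crown Mysticeti, stem
#' Mysticeti, crown Odontoceti (including its own stem), stem Odontoceti
#' excluding the sperm whale, and the sperm-whale ancestor (terminal)
#' branch.
#'
#' @param mysticeti,odontoceti tip labels of the two cetacean clades
#'   (odontoceti includes the sperm whale).
#' @param sperm_whale the sperm-whale tip label.
#' @return a scheme for [label_branch_categories()].
#' @export
cetacean_scheme <- function(mysticeti, odontoceti, sperm_whale) {
  odont_no_sperm <- setdiff(odontoceti, sperm_whale)
  list(
    functional = sel_rest(),
    cetacea_stem = sel_stem(c(mysticeti, odontoceti)),
    mysticeti = sel_clade(mysticeti, include_stem = TRUE),
    mysticeti_stem = sel_stem(mysticeti),
    odontoceti = sel_clade(odontoceti, include_stem = TRUE),
    odontoceti_stem = sel_stem(odont_no_sperm),
    sperm_whale_ancestor = sel_tips(sperm_whale))
}

# per-branch omega truth of the cetacea fixture: strong purifying selection
# while the gene is functional, relaxed (neutral) evolution after loss,
# intermediate values on the stems where loss happened partway
.cetacea_omegas <- c(
  mysticeti = 0.8, odontoceti_crown = 0.3, sperm_whale = 0.4,
  cetacea = 0.10,
  bowhead_whale = 1, gray_whale = 1, antarctic_minke_whale = 1,
  minke_whale = 1, balaenoptera = 1, balaenopteroidea = 1,
  yangtze_river_dolphin = 1, finless_porpoise = 1, beluga_whale = 1,
  killer_whale = 1, white_sided_dolphin = 1, bottlenose_dolphin = 1,
  humpback_dolphin = 1, tursiops_sousa = 1, delphininae = 1,
  delphinidae = 1, phocoenoidea = 1, delphinoidea = 1,
  .default = 0.08)

.cetacea_lesions <- list(
  # shared 2-nt deletion: every sampled odontocete except the sperm whale
  yangtze_river_dolphin = list(lesion_spec("deletion", 0.35, 2L),
                               lesion_spec("nonsense", 0.30),
                               lesion_spec("nonsense", 0.60)),
  finless_porpoise = list(lesion_spec("deletion", 0.35, 2L),
                          lesion_spec("nonsense", 0.45)),
  beluga_whale = list(lesion_spec("deletion", 0.35, 2L),
                      lesion_spec("deletion", 0.06, 1L)),
  killer_whale = list(lesion_spec("deletion", 0.35, 2L)),
  white_sided_dolphin = list(lesion_spec("deletion", 0.35, 2L)),
  bottlenose_dolphin = list(lesion_spec("deletion", 0.35, 2L)),
  humpback_dolphin = list(lesion_spec("deletion", 0.35, 2L)),
  # sperm whale: private premature stop mid-gene + 1-nt insertion near end
  sperm_whale = list(lesion_spec("nonsense", 0.50),
                     lesion_spec("insertion", 0.92, 1L)),
  # mysticetes: shared 1-nt deletion near the 5' end (the minke whale is
  # unscorable there), plus private indels
  bowhead_whale = list(lesion_spec("deletion", 0.10, 1L)),
  gray_whale = list(lesion_spec("deletion", 0.10, 1L),
                    lesion_spec("insertion", 0.04, 1L)),
  antarctic_minke_whale = list(lesion_spec("deletion", 0.10, 1L),
                               lesion_spec("insertion", 0.55, 2L)))

.fixture_flanks <- function(seed, n_up = 2L, n_down = 2L, len = 600L) {
  with_seed(seed, {
    up <- stats::setNames(
      vapply(seq_len(n_up), function(i) .random_dna(len), character(1)),
      c("cpeb2_like", "neighbor_up")[seq_len(n_up)])
    down <- stats::setNames(
      vapply(seq_len(n_down), function(i) .random_dna(len), character(1)),
      c("neighbor_down", "otop1_like")[seq_len(n_down)])
    list(upstream = up, downstream = down)
  })
}

.write_fixture_common <- function(dir, ref, loci, tree_txt, read_sets,
                                  lesion_truth, statuses_truth, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(c(ref_cds = ref$cds, ref_utr5 = ref$utr5,
                ref_utr3 = ref$utr3), file.path(dir, "reference.fasta"))
  write_fasta(vapply(loci, `[[`, character(1), "seq"),
              file.path(dir, "loci.fasta"))
  if (!is.null(tree_txt)) writeLines(tree_txt, file.path(dir, "tree.nwk"))
  if (length(read_sets) > 0L) {
    dir.create(file.path(dir, "reads"), showWarnings = FALSE)
    for (nm in names(read_sets))
      write_fastq(read_sets[[nm]], file.path(dir, "reads",
                                             paste0(nm, ".fastq")))
  }
  write_tsv(lesion_truth, file.path(dir, "truth_lesions.tsv"))
  jsonlite::write_json(list(statuses = as.list(statuses_truth)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a bundled fixture
#'
#' Writes a deterministic, self-contained run directory. Available
#' fixtures: `"cetacea"` (15 taxa, three independent inactivation events,
#' one taxon unscorable from assembly gaps), `"polymorphic_pika"` (one
#' taxon, premature stop segregating at 50/50 in the reads),
#' `"truncation"` (one taxon whose locus is interrupted mid-gene), and
#' `"clean"` (six taxa, no lesions).
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed integer seed (default 20191011).
#' @param n_codons CDS size in codons, terminal stop excluded
#'   (default 479, i.e. a 1440-nt CDS).
#' @param depth per-read-set coverage depth (default 15).
#' @return the directory, invisibly; the written `config.json` is directly
#'   runnable with [run_pipeline()].
#' @export
make_fixture <- function(name, dir, seed = 20191011L, n_codons = 479L,
                         depth = 15) {
  name <- match.arg(name, c("cetacea", "polymorphic_pika", "truncation",
                            "clean"))
  switch(name,
         cetacea = .fixture_cetacea(dir, seed, n_codons, depth),
         polymorphic_pika = .fixture_pika(dir, seed, n_codons),
         truncation = .fixture_truncation(dir, seed, n_codons),
         clean = .fixture_clean(dir, seed, n_codons, depth))
}

.build_reference <- function(cds_sense, seed) {
  with_seed(seed, {
    utr5 <- .random_dna(150L)
    utr3 <- .random_dna(150L)
  })
  reference_gene(paste0(cds_sense, "TAA"), utr5 = utr5, utr3 = utr3,
                 name = "focal_gene", taxon = "cattle")
}

.fixture_cetacea <- function(dir, seed, n_codons, depth) {
  pi <- fixture_codon_freqs()
  tree <- ape::read.tree(text = .cetacea_newick)
  root <- random_root_cds(n_codons, seed)
  spec <- evolution_spec(tree, .cetacea_omegas, kappa = 2.5,
                         root_cds = root, seed = seed + 1L,
                         codon_freqs = pi)
  sim <- simulate_cds_evolution(spec)
  ref <- .build_reference(sim$cds[["cattle"]], seed + 2L)
  flanks <- .fixture_flanks(seed + 3L)

  loci <- list()
  lesion_truth <- list()
  read_sets <- list()
  statuses <- stats::setNames(rep("intact", length(tree$tip.label)),
                              tree$tip.label)
  for (tx in tree$tip.label) {
    cds <- paste0(sim$cds[[tx]], "TAA")
    les <- .cetacea_lesions[[tx]]
    inj <- if (is.null(les)) list(seq = cds, truth = .empty_truth())
      else inject_lesions(cds, les, seed = seed + 10L)
    if (nrow(inj$truth) > 0L) statuses[tx] <- "eroded"
    gene_feature <- paste0(ref$utr5, inj$seq, ref$utr3)
    n_runs <- NULL
    if (tx == "minke_whale") {
      # assembly gap over the 5' third of the gene feature: coding status
      # cannot be assessed there (covers the shared mysticete deletion site)
      n_runs <- data.frame(at = 0.02,
                           length = round(0.33 * nchar(gene_feature)),
                           relative_to = "cds")
      statuses[tx] <- "inconclusive"
    }
    bl <- build_locus(gene_feature, flanks, intergenic_length = 250L,
                      n_runs = n_runs, strand = "+", fragment_cds = TRUE,
                      seed = seed + match(tx, tree$tip.label),
                      name = tx)
    loci[[tx]] <- bl$locus
    if (nrow(inj$truth) > 0L) {
      t <- inj$truth
      t$taxon <- tx
      lesion_truth[[tx]] <- t
      for (rs in 1:2) {
        sr <- simulate_reads(bl$locus, depth = depth, read_len = 100L,
                             error_rate = 0.002,
                             seed = seed + 100L * rs +
                               match(tx, tree$tip.label))
        read_sets[[paste0(tx, ".sra", rs)]] <- sr$reads
      }
    }
  }
  truth <- if (length(lesion_truth) > 0L) {
    do.call(rbind, lesion_truth)
  } else .empty_truth()

  config <- list(
    fixture = "cetacea",
    reference = "reference.fasta",
    loci = "loci.fasta",
    tree = "tree.nwk",
    reads_dir = "reads",
    stages = c("annotate", "validate", "events", "selection"),
    scheme = "cetacea",
    scheme_groups = .cetacea_groups[c("mysticeti", "odontoceti",
                                      "sperm_whale")],
    focal_categories = list("cetacea_stem"),
    params = list(min_coverage = 0.2, min_unambiguous_coverage = 0.9,
                  flank_nt = 50, min_reads = 3, conf_thr = 0.8),
    seed = seed)
  .write_fixture_common(dir, ref, loci, .cetacea_newick, read_sets,
                        truth, statuses, config)
}

.fixture_pika <- function(dir, seed, n_codons) {
  root <- random_root_cds(n_codons, seed + 40L)
  cds <- paste0(root, "TAA")
  ref <- .build_reference(root, seed + 41L)
  flanks <- .fixture_flanks(seed + 42L)
  inj <- inject_lesions(cds, list(lesion_spec("nonsense", 0.5)),
                        seed = seed + 43L)
  wild_feature <- paste0(ref$utr5, cds, ref$utr3)
  mut_feature <- paste0(ref$utr5, inj$seq, ref$utr3)
  bl_mut <- build_locus(mut_feature, flanks, seed = seed + 44L,
                        name = "pika")
  bl_wild <- build_locus(wild_feature, flanks, seed = seed + 44L,
                         name = "pika_wild")
  # heterozygous locus: half the reads from each allele; long (250 nt)
  # reads so that enough reads span the site with full anchors
  sr <- simulate_reads(bl_mut$locus, depth = 50, read_len = 250L,
                       error_rate = 0,
                       allele_mix = c(mutant = 0.5, wild = 0.5),
                       alleles = c(mutant = bl_mut$locus$seq,
                                   wild = bl_wild$locus$seq),
                       seed = seed + 45L)
  truth <- inj$truth
  truth$taxon <- "pika"
  config <- list(
    fixture = "polymorphic_pika",
    reference = "reference.fasta", loci = "loci.fasta",
    reads_dir = "reads",
    stages = c("annotate", "validate"),
    params = list(min_coverage = 0.2, min_unambiguous_coverage = 0.9,
                  flank_nt = 20, min_reads = 3, conf_thr = 0.8),
    seed = seed)
  .write_fixture_common(dir, ref, list(pika = bl_mut$locus), NULL,
                        list(pika.sra1 = sr$reads), truth,
                        c(pika = "eroded"), config)
}

.fixture_truncation <- function(dir, seed, n_codons) {
  root <- random_root_cds(n_codons, seed + 60L)
  cds <- paste0(root, "TAA")
  ref <- .build_reference(root, seed + 61L)
  flanks <- .fixture_flanks(seed + 62L)
  inj <- inject_lesions(cds, list(lesion_spec("deletion", 0.06, 1L)),
                        seed = seed + 63L)
  # the locus is interrupted: everything downstream of 55% of the CDS is
  # unrelated sequence
  cut <- floor(0.55 * nchar(inj$seq))
  broken <- with_seed(seed + 64L, paste0(substr(inj$seq, 1L, cut),
                                         .random_dna(nchar(inj$seq) - cut)))
  feature <- paste0(ref$utr5, broken, ref$utr3)
  bl <- build_locus(feature, flanks, seed = seed + 65L, name = "beluga_like")
  truth <- inj$truth
  truth$taxon <- "beluga_like"
  config <- list(
    fixture = "truncation",
    reference = "reference.fasta", loci = "loci.fasta",
    stages = c("annotate"),
    params = list(min_coverage = 0.2, min_unambiguous_coverage = 0.9),
    seed = seed)
  .write_fixture_common(dir, ref, list(beluga_like = bl$locus), NULL,
                        list(), truth, c(beluga_like = "eroded"), config)
}

.fixture_clean <- function(dir, seed, n_codons, depth) {
  nwk <- paste0("((a:0.05,b:0.05):0.03,(c:0.04,(d:0.03,(e:0.02,f:0.02)",
                ":0.01):0.01):0.03);")
  tree <- ape::read.tree(text = nwk)
  root <- random_root_cds(n_codons, seed + 80L)
  spec <- evolution_spec(tree, 0.1, kappa = 2.5, root_cds = root,
                         seed = seed + 81L,
                         codon_freqs = fixture_codon_freqs())
  sim <- simulate_cds_evolution(spec)
  ref <- .build_reference(sim$cds[["a"]], seed + 82L)
  flanks <- .fixture_flanks(seed + 83L)
  loci <- list()
  read_sets <- list()
  for (tx in tree$tip.label) {
    feature <- paste0(ref$utr5, sim$cds[[tx]], "TAA", ref$utr3)
    bl <- build_locus(feature, flanks, seed = seed + 90L + match(
      tx, tree$tip.label), name = tx)
    loci[[tx]] <- bl$locus
    sr <- simulate_reads(bl$locus, depth = depth, read_len = 100L,
                         error_rate = 0.002,
                         seed = seed + 95L + match(tx, tree$tip.label))
    read_sets[[paste0(tx, ".sra1")]] <- sr$reads
  }
  config <- list(
    fixture = "clean",
    reference = "reference.fasta", loci = "loci.fasta", tree = "tree.nwk",
    reads_dir = "reads",
    stages = c("annotate", "validate", "events"),
    params = list(min_coverage = 0.2, min_unambiguous_coverage = 0.9,
                  flank_nt = 50, min_reads = 3, conf_thr = 0.8),
    seed = seed)
  .write_fixture_common(dir, ref, loci, nwk, read_sets, .empty_truth(),
                        stats::setNames(rep("intact", 6L), tree$tip.label),
                        config)
}
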