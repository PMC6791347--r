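# End-to-end orchestration: annotate every locus against the reference,
# validate called mutations against reads, count independent loss events on
# the species tree, and run the branch-category selection analysis. Every
# intermediate is written to the run directory as a plain-text file; the
# summary is machine-readable JSON.

#' Uncovered reference-CDS intervals of a mapped alignment
#'
#' Positions of the reference CDS not unambiguously covered (aligned to a
#' gap or N), merged into intervals; the positions a taxon cannot be
#' scored at when building the mutation matrix.
#'
#' @param aln a [map_reference_cds()] result.
#' @return data frame with `start`, `end` (1-based reference-CDS
#'   coordinates).
#' @export
uncovered_intervals <- function(aln) {
  gc <- strsplit(aln$region_aln, "")[[1L]]
  L <- aln$cds_span[2] - aln$cds_span[1] + 1L
  cov <- rep(FALSE, L)
  in_cds <- !is.na(aln$ref_coord) & aln$ref_coord >= aln$cds_span[1] &
    aln$ref_coord <= aln$cds_span[2]
  pos <- aln$ref_coord[in_cds] - aln$cds_span[1] + 1L
  cov[pos] <- gc[in_cds] %in% .nucs
  r <- .runs(!cov)
  if (nrow(r) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = r$start, end = r$start + r$len - 1L)
}

.read_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$base_dir <- base
  }
  config$base_dir <- config$base_dir %||% "."
  config$stages <- as.character(config$stages %||% character(0))
  config$params <- config$params %||% list()
  config
}

.cfg_path <- function(config, field) {
  p <- config[[field]]
  if (is.null(p)) return(NULL)
  if (!file.exists(p)) p <- file.path(config$base_dir, p)
  p
}

.load_reads <- function(reads_dir) {
  if (is.null(reads_dir) || !dir.exists(reads_dir)) return(list())
  files <- list.files(reads_dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                      full.names = TRUE)
  sets <- lapply(files, read_fastq)
  names(sets) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(files))
  sets
}

#' Run the gene-loss inference pipeline
#'
#' Executes the enabled stages in dependency order (annotate, validate,
#' events, selection), writes every intermediate to `out_dir` (mutation
#' table, statuses, verdicts, events, selection table, codon alignment,
#' labeled tree) plus a machine-readable `summary.json` and a parameter
#' log. A stage failure aborts with the stage name; downstream stages are
#' skipped.
#'
#' @param config a list or a path to a JSON config (as written by
#'   [make_fixture()]): fields `reference`, `loci`, `tree`, `reads_dir`,
#'   `stages`, `scheme` / `scheme_groups`, `focal_categories`, `params`,
#'   `seed`.
#' @param out_dir run directory (default `config$out_dir` or a tempdir).
#' @return the summary, invisibly (a list; also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- .read_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), paste0("geneloss-run-",
                                format(Sys.time(), "%H%M%S")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  stages <- config$stages
  summary <- list(stages = stages, params = p, seed = config$seed,
                  package_version = as.character(utils::packageVersion(
                    "geneloss")))
  log_lines <- c(sprintf("geneloss %s", summary$package_version),
                 sprintf("stages: %s", paste(stages, collapse = ", ")),
                 sprintf("seed: %s", config$seed %||% "none"),
                 sprintf("params: %s", jsonlite::toJSON(p, auto_unbox = TRUE)))

  if (length(stages) == 0L) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    return(invisible(summary))
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  ref_seqs <- read_fasta(.cfg_path(config, "reference"))
  reference <- reference_gene(ref_seqs[["ref_cds"]],
                              utr5 = ref_seqs[["ref_utr5"]] %||% "",
                              utr3 = ref_seqs[["ref_utr3"]] %||% "",
                              name = "reference")
  loci <- read_fasta(.cfg_path(config, "loci"))
  taxa <- names(loci)
  tree <- if (!is.null(config$tree))
    ape::read.tree(.cfg_path(config, "tree"))
  read_sets <- .load_reads(.cfg_path(config, "reads_dir"))

  alns <- list()
  mutations <- list()
  statuses <- stats::setNames(rep(NA_character_, length(taxa)), taxa)
  truncations <- list()

  # --- annotate -------------------------------------------------------
  if ("annotate" %in% stages) run_stage("annotate", {
    for (tx in taxa) {
      aln <- tryCatch(
        map_reference_cds(reference, loci[[tx]],
                          min_coverage = p$min_coverage %||% 0.2),
        error = function(e) NULL)
      if (is.null(aln)) {
        statuses[tx] <- "inconclusive"
        next
      }
      alns[[tx]] <- aln
      mut <- call_inactivating_mutations(aln)
      trunc <- detect_truncation(aln,
                                 window_nt = p$window_nt %||% 60L,
                                 step_nt = p$step_nt %||% 15L,
                                 high_thr = p$high_thr %||% 70,
                                 low_thr = p$low_thr %||% 50)
      if (!is.null(trunc) && !trunc$inconclusive) {
        truncations[[tx]] <- trunc
        mut <- rbind(mut, truncation_as_mutation(trunc, aln))
      }
      mutations[[tx]] <- mut
      statuses[tx] <- classify_coding_status(
        mut, aln, p$min_unambiguous_coverage %||% 0.9)
    }
    mut_tab <- .bind_mutation_tables(mutations)
    write_tsv(mut_tab, file.path(out_dir, "mutations.tsv"))
    write_tsv(data.frame(taxon = taxa, status = statuses,
                         coverage = vapply(taxa, function(tx)
                           if (is.null(alns[[tx]])) NA_real_
                           else alns[[tx]]$coverage, numeric(1)),
                         unambiguous_coverage = vapply(taxa, function(tx)
                           if (is.null(alns[[tx]])) NA_real_
                           else alns[[tx]]$unambiguous_coverage,
                           numeric(1)),
                         row.names = NULL),
              file.path(out_dir, "status.tsv"))
    summary$statuses <- as.list(statuses)
    summary$n_mutations <- vapply(taxa, function(tx)
      if (is.null(mutations[[tx]])) 0L else nrow(mutations[[tx]]),
      integer(1))
  })

  # --- validate -------------------------------------------------------
  if ("validate" %in% stages) run_stage("validate", {
    verdicts <- list()
    for (tx in taxa) {
      mut <- mutations[[tx]]
      if (is.null(mut) || nrow(mut) == 0L) next
      vm <- mut[!is.na(mut$region_coord), , drop = FALSE]
      if (nrow(vm) == 0L) next
      tx_sets <- read_sets[grepl(paste0("^", tx, "\\."), names(read_sets))]
      if (length(tx_sets) == 0L) {
        warning("no reads for taxon ", tx, "; verdicts are no_data")
        v <- data.frame(mutation = seq_len(nrow(vm)), kind = vm$kind,
                        ref_coord = vm$ref_coord, read_set = NA_character_,
                        verdict = "no_data",
                        support_fraction = NA_real_,
                        consensus = "no_data", stringsAsFactors = FALSE)
      } else {
        v <- validate_all(vm, alns[[tx]], tx_sets,
                          flank_nt = p$flank_nt %||% 50L,
                          min_reads = p$min_reads %||% 3L,
                          conf_thr = p$conf_thr %||% 0.8)
      }
      v$taxon <- tx
      verdicts[[tx]] <- v
    }
    vt <- if (length(verdicts) > 0L) do.call(rbind, verdicts) else
      data.frame()
    if (nrow(vt) > 0L) rownames(vt) <- NULL
    write_tsv(vt, file.path(out_dir, "verdicts.tsv"))
    summary$verdicts <- if (nrow(vt) > 0L)
      stats::setNames(as.list(tapply(vt$consensus,
                                     paste(vt$taxon, vt$kind, vt$ref_coord),
                                     `[`, 1L)), NULL) else list()
    summary$verdict_table <- vt
  })

  # --- events ---------------------------------------------------------
  if ("events" %in% stages) run_stage("events", {
    if (is.null(tree)) stop("events stage needs a species tree")
    uncov <- lapply(alns, uncovered_intervals)
    mm <- build_mutation_matrix(mutations, statuses, uncovered = uncov)
    ev <- count_independent_losses(mm, tree)
    write_tsv(ev$branches, file.path(out_dir, "events.tsv"))
    summary$loss_events <- ev$count
    summary$loss_branches <- ev$branches$description
  })

  # --- selection ------------------------------------------------------
  if ("selection" %in% stages) run_stage("selection", {
    if (is.null(tree)) stop("selection stage needs a species tree")
    excluded <- names(statuses)[statuses == "inconclusive"]
    excluded <- union(excluded, names(truncations))
    sel_taxa <- setdiff(taxa, excluded)
    cds_set <- vapply(sel_taxa, function(tx)
      frame_corrected_cds(alns[[tx]]), character(1))
    aln_cod <- translation_align(cds_set)
    write_codon_alignment(aln_cod, file.path(out_dir, "alignment.fasta"))
    sel_tree <- ape::drop.tip(tree, setdiff(tree$tip.label, sel_taxa))
    scheme <- .resolve_scheme(config, sel_tree)
    ltree <- label_branch_categories(sel_tree, scheme)
    write_labeled_tree(ltree, file.path(out_dir, "labeled_tree.nwk"))
    focal <- unlist(config$focal_categories %||%
                      setdiff(unique(ltree$categories), "functional"))
    rows <- lapply(focal, function(fc) {
      r <- test_branch_category(aln_cod, ltree, fc,
                                opts = config$fit_opts %||% list())
      data.frame(category = fc, omega = r$omega,
                 omega_background = r$omega_background, kappa = r$kappa,
                 statistic = r$lrt$statistic, df = r$lrt$df,
                 p_value = r$lrt$p_value, stringsAsFactors = FALSE)
    })
    sel <- do.call(rbind, rows)
    write_tsv(sel, file.path(out_dir, "selection.tsv"))
    summary$selection <- sel
    summary$selection_excluded <- excluded
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(summary)
}

.bind_mutation_tables <- function(mutations) {
  keep <- !vapply(mutations, is.null, logical(1))
  if (!any(keep)) {
    out <- .empty_mutations()
    out$taxon <- character(0)
    return(out)
  }
  rows <- lapply(names(mutations)[keep], function(tx) {
    m <- mutations[[tx]]
    if (nrow(m) == 0L) return(NULL)
    m$taxon <- tx
    m
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- .empty_mutations()
    out$taxon <- character(0)
  }
  rownames(out) <- NULL
  out
}

.resolve_scheme <- function(config, tree) {
  if (is.null(config$scheme)) {
    return(list(all = sel_rest()))
  }
  if (identical(config$scheme, "cetacea")) {
    g <- config$scheme_groups
    keep <- function(x) intersect(unlist(x), tree$tip.label)
    return(cetacean_scheme(keep(g$mysticeti), keep(g$odontoceti),
                           keep(g$sperm_whale)))
  }
  stop("unknown scheme: ", config$scheme)
}
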