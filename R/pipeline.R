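#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()]. Two modes exist:
#' `"simulate"` (default) generates the genome, annotations and read
#' libraries from `sim`; `"files"` reads them from the paths in `inputs`
#' (`genome`, `reads` — a named vector of FASTQ paths per library — and
#' optionally `known_mature`, `ncrna_bed`, `repeats_bed`).
#'
#' @param mode `"simulate"` or `"files"`.
#' @param sim A [sim_config()] (simulate mode).
#' @param inputs Named list of input paths (files mode).
#' @param outdir Output directory.
#' @param libraries Library labels in the 2x2 design.
#' @param adapter Adapter for trimming; defaults to the simulated one.
#' @param dispersion,p_max,min_abs_lfc DE parameters.
#' @param ir An [ir_params()].
#' @param n_genes,n_categories Synthetic gene/annotation scale for the
#'   target-prediction and enrichment stages.
#' @param target_cutoff ddG retention cutoff (kcal/mol).
#' @param ct Optional qPCR Ct tibble (see [qpcr_ddct()]); when `NULL` the
#'   qPCR stage is skipped.
#' @param seed Global seed (simulate mode uses `sim$seed`).
#' @return A validated list of class `tormir_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            sim = sim_config(), inputs = list(),
                            outdir = tempfile("tormir_run_"),
                            libraries = c("HB", "AB", "HA", "AA"),
                            adapter = NULL, dispersion = 0.1, p_max = 0.01,
                            min_abs_lfc = 1, ir = ir_params(),
                            n_genes = 8, n_categories = 4,
                            target_cutoff = -10, ct = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(list(mode = mode, sim = sim, inputs = inputs,
                        outdir = outdir, libraries = libraries,
                        adapter = adapter %||% sim$adapter_sequence,
                        dispersion = dispersion, p_max = p_max,
                        min_abs_lfc = min_abs_lfc, ir = ir,
                        n_genes = n_genes, n_categories = n_categories,
                        target_cutoff = target_cutoff, ct = ct,
                        seed = as.integer(seed)),
                   class = "tormir_pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$mode == "files") {
    if (is.null(cfg$inputs$genome)) {
      abort("validation error: inputs$genome path is required in files mode")
    }
    if (is.null(cfg$inputs$reads)) {
      abort("validation error: inputs$reads FASTQ paths are required in files mode")
    }
    missing <- c(cfg$inputs$genome, unlist(cfg$inputs$reads))
    missing <- missing[!file.exists(missing)]
    if (length(missing)) {
      abort(paste("validation error: missing input file(s):",
                  paste(missing, collapse = ", ")))
    }
  }
  stopifnot(cfg$dispersion >= 0, cfg$p_max > 0, cfg$p_max <= 1)
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override [pipeline_config()] defaults; the
#' nested `sim` block overrides [sim_config()] defaults.
#'
#' @param path YAML path.
#' @return A `tormir_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- y
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

stage_files <- function(outdir, stage, files) {
  tibble(stage = stage, file = unname(files),
         md5 = unname(tools::md5sum(files)))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> preprocess -> map/classify -> hairpin
#' discovery -> differential expression -> target prediction -> enrichment
#' -> qPCR (optional), writing every intermediate to `outdir` and recording
#' a manifest of stages, parameters and file checksums. Any stage failure
#' aborts with the stage name; outputs written so far are retained.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `tormir_run`: all stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list(config = config)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  # --- simulate / load inputs ------------------------------------------
  if (config$mode == "simulate") {
    sim <- run_stage("simulate", {
      s <- simulate_genome(config$sim)
      reads <- bind_rows(lapply(config$libraries,
                                function(l) simulate_reads(s, l)))
      paths <- write_simulation(s, file.path(config$outdir, "sim"))
      for (l in config$libraries) {
        fq <- file.path(config$outdir, "sim", paste0(l, ".fastq"))
        write_fastq(reads[reads$library == l, ], fq)
        paths <- c(paths, setNames(fq, paste0("fastq_", l)))
      }
      list(sim = s, reads = reads, paths = paths)
    })
    results$sim <- sim$sim
    raw_reads <- sim$reads
    genome <- sim$sim$genome
    known_mature <- sim$sim$known_mature
    ncrna <- sim$sim$ncrna[, c("sequence", "subclass")]
    repeats <- sim$sim$repeats
    manifest$simulate <- stage_files(config$outdir, "simulate", sim$paths)
  } else {
    loaded <- run_stage("load", {
      genome <- Biostrings::readDNAStringSet(config$inputs$genome)
      reads <- bind_rows(imap(config$inputs$reads, function(p, l) {
        mutate(read_fastq(p), library = l)
      }))
      list(genome = genome, reads = reads)
    })
    genome <- loaded$genome
    raw_reads <- loaded$reads
    known_mature <- if (!is.null(config$inputs$known_mature)) {
      km <- read_fasta(config$inputs$known_mature)
      tibble(mirna_id = names(km), sequence = unname(km))
    } else NULL
    ncrna <- NULL
    repeats <- NULL
  }

  # --- preprocess -------------------------------------------------------
  pre <- run_stage("preprocess", {
    trimmed <- trim_adapter(raw_reads, config$adapter)
    clean <- clean_reads(trimmed)
    collapsed <- collapse_unique(clean)
    stats <- library_stats(clean)
    f1 <- file.path(config$outdir, "collapsed.fa")
    f2 <- file.path(config$outdir, "library_stats.tsv")
    f3 <- file.path(config$outdir, "counts_unique.tsv")
    write_collapsed_fasta(collapsed, f1)
    readr::write_tsv(stats, f2)
    readr::write_tsv(collapsed, f3)
    list(clean = clean, collapsed = collapsed, stats = stats,
         files = c(f1, f2, f3))
  })
  results$collapsed <- pre$collapsed
  results$stats <- pre$stats
  manifest$preprocess <- stage_files(config$outdir, "preprocess", pre$files)

  # --- map & classify ---------------------------------------------------
  mc <- run_stage("map_classify", {
    idx <- genome_index(genome)
    hits <- map_reads(pre$collapsed, idx)
    retained <- filter_hits(pre$collapsed, hits)
    classified <- classify_reads(retained, hits, known_mature = known_mature,
                                 ncrna = ncrna, repeats = repeats)
    tab <- classification_table(classified, libraries = config$libraries)
    f1 <- file.path(config$outdir, "hits.tsv")
    f2 <- file.path(config$outdir, "classification.tsv")
    readr::write_tsv(hits, f1)
    readr::write_tsv(tab, f2)
    list(idx = idx, hits = hits, retained = retained,
         classified = classified, table = tab, files = c(f1, f2))
  })
  results$hits <- mc$hits
  results$classified <- mc$classified
  results$classification_table <- mc$table
  manifest$map_classify <- stage_files(config$outdir, "map_classify", mc$files)

  # --- hairpin discovery ------------------------------------------------
  disc <- run_stage("discover", {
    cand <- mc$classified[mc$classified$class %in% c("known_miRNA", "unknown"), ]
    cand_hits <- mc$hits[mc$hits$sequence %in% cand$sequence, ]
    res <- discover_mirna(cand_hits, cand, genome,
                          known_mature = known_mature, params = config$ir)
    f1 <- file.path(config$outdir, "hairpins.tsv")
    readr::write_tsv(select(res, -dplyr::any_of("pairs")), f1)
    list(candidates = res, files = f1)
  })
  results$hairpins <- disc$candidates
  manifest$discover <- stage_files(config$outdir, "discover", disc$files)

  # --- differential expression -----------------------------------------
  de <- run_stage("de", {
    cand <- disc$candidates
    if (nrow(cand) == 0) {
      list(counts = NULL, de = NULL, files = character(0))
    } else {
    matures <- bind_rows(lapply(c("5p", "3p"), function(arm) {
      s <- cand[[paste0("mature", arm, "_start")]]
      e <- cand[[paste0("mature", arm, "_end")]]
      P <- cand$precursor_end - cand$precursor_start
      gs <- ifelse(cand$orientation == "+", cand$precursor_start + s - 1L,
                   cand$precursor_start + P - e)
      ge <- ifelse(cand$orientation == "+", cand$precursor_start + e,
                   cand$precursor_start + P - s + 1L)
      tibble(mirna_id = paste0(cand$candidate_id, "-", arm),
             contig = cand$contig, start = gs, end = ge)
    }))
    counts <- quantify_mature(mc$classified, mc$hits, matures,
                              libraries = config$libraries)
    totals <- vapply(config$libraries, function(l) {
      sum(pre$collapsed[[l]][pre$collapsed$sequence %in% mc$hits$sequence])
    }, numeric(1))
    de <- test_de(counts, totals = totals, dispersion = config$dispersion,
                  p_max = config$p_max, min_abs_lfc = config$min_abs_lfc)
    spec <- call_specific(counts)
    f1 <- file.path(config$outdir, "mature_counts.tsv")
    f2 <- file.path(config$outdir, "de.tsv")
    f3 <- file.path(config$outdir, "specificity.tsv")
    readr::write_tsv(counts, f1)
    readr::write_tsv(as_tibble(de), f2)
    readr::write_tsv(spec, f3)
    list(counts = counts, totals = totals, de = de, specificity = spec,
         files = c(f1, f2, f3))
    }
  })
  results$mature_counts <- de$counts
  results$de <- de$de
  results$specificity <- de$specificity
  if (length(de$files)) {
    manifest$de <- stage_files(config$outdir, "de", de$files)
  }

  # --- target prediction & enrichment ----------------------------------
  tg <- run_stage("targets", {
    if (is.null(de$de) || !nrow(call_de(de$de, config$p_max,
                                        config$min_abs_lfc))) {
      list(targets = NULL, enrichment = NULL, files = character(0))
    } else {
    set.seed(config$seed)
    genes <- tibble(gene_id = sprintf("gene-%02d", seq_len(config$n_genes)),
                    sequence = vapply(seq_len(config$n_genes), function(i) {
                      random_dna(600, 0.45)
                    }, character(1)))
    utrs <- bind_rows(lapply(seq_len(nrow(genes)), function(i) {
      mutate(infer_utr(genes$sequence[i]), gene_id = genes$gene_id[i])
    }))
    sig <- call_de(de$de, config$p_max, config$min_abs_lfc)
    sig_ids <- unique(sig$feature_id)
    mirnas <- tibble(mirna_id = sig_ids)
    arm <- sub("^.*-", "", sig_ids)
    cand_id <- sub("-[53]p$", "", sig_ids)
    mirnas$sequence <- vapply(seq_along(sig_ids), function(i) {
      row <- disc$candidates[disc$candidates$candidate_id == cand_id[i], ]
      row[[paste0("mature", arm[i], "_seq")]][1]
    }, character(1))
    targets <- predict_targets(mirnas, utrs, cutoff = config$target_cutoff)
    annotation <- tibble(
      category = sprintf("path-%02d",
                         sample.int(config$n_categories, config$n_genes,
                                    replace = TRUE)),
      gene = genes$gene_id)
    enr <- enrich_hypergeom(unique(targets$gene_id[targets$retained]),
                            annotation)
    f1 <- file.path(config$outdir, "targets.tsv")
    f2 <- file.path(config$outdir, "enrichment.tsv")
    readr::write_tsv(targets, f1)
    readr::write_tsv(enr, f2)
    list(targets = targets, enrichment = enr, files = c(f1, f2))
    }
  })
  results$targets <- tg$targets
  results$enrichment <- tg$enrichment
  if (length(tg$files)) {
    manifest$targets <- stage_files(config$outdir, "targets", tg$files)
  }

  # --- qPCR (optional) --------------------------------------------------
  if (!is.null(config$ct)) {
    qp <- run_stage("qpcr", {
      targets <- setdiff(unique(config$ct$target_id), "5S")
      res <- bind_rows(lapply(targets, function(t) qpcr_ddct(config$ct, t)))
      f1 <- file.path(config$outdir, "qpcr.tsv")
      readr::write_tsv(res, f1)
      list(qpcr = res, files = f1)
    })
    results$qpcr <- qp$qpcr
    manifest$qpcr <- stage_files(config$outdir, "qpcr", qp$files)
  }

  results$manifest <- bind_rows(manifest)
  structure(results, class = "tormir_run")
}

#' @export
print.tormir_run <- function(x, ...) {
  cat("tormir pipeline run\n")
  cat("  stages:", paste(unique(x$manifest$stage), collapse = ", "), "\n")
  cat("  outputs:", nrow(x$manifest), "files in", x$config$outdir, "\n")
  invisible(x)
}

#' Write summary report tables for a pipeline run
#'
#' Emits the per-class read classification table, the differential
#' expression table, the class-proportion summary and a plain-text summary.
#' Regenerating the report from the same run is byte-identical.
#'
#' @param run A `tormir_run`.
#' @param outdir Report directory; defaults to `<run outdir>/report`.
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(run, outdir = NULL) {
  outdir <- outdir %||% file.path(run$config$outdir, "report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  tab <- run$classification_table
  f <- file.path(outdir, "classification_table.tsv")
  matched <- tab |>
    group_by(.data$library) |>
    summarise(total = sum(.data$total_reads))
  summ <- classification_summary(tab, setNames(matched$total, matched$library))
  readr::write_tsv(summ, f)
  paths <- c(paths, classification = f)

  if (!is.null(run$de)) {
    f <- file.path(outdir, "de_table.tsv")
    readr::write_tsv(as_tibble(run$de), f)
    paths <- c(paths, de = f)
  }
  if (!is.null(run$qpcr)) {
    f <- file.path(outdir, "qpcr_table.tsv")
    readr::write_tsv(run$qpcr, f)
    paths <- c(paths, qpcr = f)
  }
  f <- file.path(outdir, "summary.txt")
  lines <- c("tormir run summary",
             sprintf("libraries: %s", paste(run$config$libraries, collapse = ", ")),
             sprintf("unique reads: %d", nrow(run$collapsed)),
             sprintf("hairpin candidates: %d",
                     if (is.null(run$hairpins)) 0L else nrow(run$hairpins)))
  if (!is.null(run$de)) {
    g <- glance(run$de)
    lines <- c(lines, sprintf("significant (%s): %d", g$comparison,
                              g$n_significant))
  }
  writeLines(lines, f)
  paths <- c(paths, summary = f)
  invisible(paths)
}
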