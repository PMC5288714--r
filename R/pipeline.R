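#' Pipeline configuration
#'
#' Collects every stage parameter plus input/output paths. With
#' `simulate = TRUE` (the default) the genome, annotation, methylome and
#' reads come from the built-in simulator; otherwise `genome_fasta`,
#' `reads` (a named list of FASTQ paths) and `sample_conditions` must be
#' supplied.
#'
#' @param out_dir Output directory.
#' @param simulate Use the synthetic-data generator.
#' @param sim A [sim_config()] (simulated runs).
#' @param genome_fasta,reads,sample_conditions External inputs: reference
#'   FASTA, named list of per-sample FASTQ paths, named vector mapping
#'   sample id to condition.
#' @param gene_models_path BED12/GTF gene models (external runs; simulated
#'   runs use the generated models).
#' @param expression_genes,splicing_genes Optional plain-text gene lists for
#'   overlap statistics.
#' @param treated,control Condition labels.
#' @param trim A [trim_config()].
#' @param max_mismatches,min_coverage,window,min_sites,min_delta,p_threshold,q_threshold,mode,strong_threshold,promoter_flank,top_n
#'   Stage parameters (see the corresponding stage functions).
#' @param min_len,max_len Fragment size selection (external runs; simulated
#'   runs take them from `sim`).
#' @param seed Master seed.
#' @param log_level Logging floor (`"debug"`, `"info"`, `"warn"`, `"error"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("rrbs_run_"),
                            simulate = TRUE, sim = sim_config(),
                            genome_fasta = NULL, reads = NULL,
                            sample_conditions = NULL,
                            gene_models_path = NULL,
                            expression_genes = NULL, splicing_genes = NULL,
                            treated = "T", control = "NT",
                            trim = trim_config(),
                            max_mismatches = 2L, min_coverage = 5L,
                            window = 200L, min_sites = 3L, min_delta = 0.25,
                            p_threshold = 0.05, q_threshold = 0.01,
                            mode = "pooled", strong_threshold = 1/3,
                            promoter_flank = 1000L, top_n = 100L,
                            min_len = 40L, max_len = 350L,
                            seed = 1L, log_level = "info") {
  cfg <- as.list(environment())
  if (!simulate) {
    for (f in c("genome_fasta", "reads", "sample_conditions"))
      if (is.null(cfg[[f]])) stopf("external runs require `%s`", f)
  }
  structure(cfg, class = "pipeline_config")
}

.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$sim <- unclass(snap$sim)
  snap$trim <- unclass(snap$trim)
  snap$sim$dmr_plan <- if (!is.null(snap$sim$dmr_plan))
    nrow(snap$sim$dmr_plan) else 0L
  snap
}

#' Run the full RRBS pipeline
#'
#' Executes digest -> (simulate) -> trim -> align -> call -> DMR ->
#' annotate -> report, writing every stage's outputs under
#' `config$out_dir` before the next stage begins. A run manifest (counts
#' per stage, config snapshot, version, timestamps) is always written, even
#' on failure.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `rrbs_run` with the manifest and all
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  old <- options(rrbspipe.log_level = config$log_level)
  on.exit(options(old), add = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(packageVersion("rrbspipe")),
                   started = format(Sys.time(), usetz = TRUE),
                   config = .config_snapshot(config),
                   counts = list(), status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  on.exit(write_manifest(), add = TRUE)
  stage <- function(name, expr) {
    rrbs_log("info", "stage: ", name)
    tryCatch(expr, error = function(e) {
      manifest$status <<- sprintf("failed at stage '%s'", name)
      write_manifest()
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  sim <- config$sim
  if (config$simulate) {
    gen <- stage("generate", generate_genome(sim))
    genome <- gen$genome; genes <- gen$genes; islands <- gen$islands
    write_genome_fasta(genome, file.path(config$out_dir, "genome.fa"))
    write_gene_models_bed12(genes, file.path(config$out_dir, "genes.bed"))
    conditions <- setNames(
      rep(names(sim$conditions), sim$conditions),
      unlist(lapply(names(sim$conditions), function(cn)
        sprintf("%s_%d", cn, seq_len(sim$conditions[[cn]])))))
    min_len <- sim$min_len; max_len <- sim$max_len
    treated <- sim$treated; control <- sim$control
  } else {
    genome <- stage("load-genome", read_genome_fasta(config$genome_fasta))
    genes <- if (!is.null(config$gene_models_path))
      stage("load-genes", read_gene_models(config$gene_models_path)) else NULL
    islands <- NULL
    conditions <- config$sample_conditions
    min_len <- config$min_len; max_len <- config$max_len
    treated <- config$treated; control <- config$control
  }

  fragments <- stage("digest",
                     digest_genome(genome, min_len = min_len,
                                   max_len = max_len))
  write_fragments(fragments, file.path(config$out_dir, "fragments.tsv"))
  manifest$counts$fragments <- nrow(fragments)

  if (is.null(islands)) {
    islands <- stage("cgi", detect_cpg_islands(genome))
  }
  write_bed3(islands, file.path(config$out_dir, "cgi.bed"))
  manifest$counts$cpg_islands <- nrow(islands)

  raw_reads <- list(); truths <- list(); methylome_truth <- NULL
  if (config$simulate) {
    methylome_truth <- stage("methylome",
                             generate_methylome(genome, fragments, islands,
                                                sim$dmr_plan, sim))
    write_truth_tables(methylome_truth, dir = config$out_dir)
    for (sm in names(conditions)) {
      r <- stage(paste0("simulate:", sm),
                 simulate_reads(fragments, methylome_truth, sm))
      write_fastq(r$reads, file.path(config$out_dir,
                                     sprintf("%s.fastq.gz", sm)))
      write_truth_tables(methylome_truth, r$truth, config$out_dir, sm)
      raw_reads[[sm]] <- r$reads
      truths[[sm]] <- r$truth
    }
  } else {
    for (sm in names(conditions))
      raw_reads[[sm]] <- stage(paste0("load-reads:", sm),
                               read_fastq(config$reads[[sm]]))
  }
  manifest$counts$reads_in <- vapply(raw_reads, nrow, 0L)

  index <- build_converted_indices(fragments)
  methylomes <- list(); alignments <- list(); qc <- list()
  for (sm in names(conditions)) {
    tr <- stage(paste0("trim:", sm), trim_reads(raw_reads[[sm]], config$trim))
    al <- stage(paste0("align:", sm),
                align_reads(tr, index, config$max_mismatches))
    write_alignments(al, file.path(config$out_dir,
                                   sprintf("%s.alignments.tsv", sm)))
    me <- stage(paste0("call:", sm),
                call_sites(al[al$status == "unique", , drop = FALSE],
                           fragments, genome, config$min_coverage, sm))
    write_cytosine_report(me, file.path(config$out_dir,
                                        sprintf("%s.cytosines.tsv", sm)))
    write_bedgraph(me, config$out_dir, sm)
    st <- table(factor(al$status, levels = c("unique", "ambiguous",
                                             "unmapped")))
    manifest$counts[[paste0("sample_", sm)]] <- list(
      trimmed = nrow(tr), unique = as.integer(st[["unique"]]),
      ambiguous = as.integer(st[["ambiguous"]]),
      unmapped = as.integer(st[["unmapped"]]),
      sites_retained = nrow(me))
    methylomes[[sm]] <- me
    alignments[[sm]] <- al
    qc[[sm]] <- qc_summary(me)
  }

  profile <- stage("profile",
                   chromosome_profile(methylomes, conditions, treated,
                                      control))
  features <- stage("features",
                    feature_average(methylomes[[1]], genes, islands,
                                    config$promoter_flank))
  ctrl_ids <- names(conditions)[conditions == control]
  trt_ids <- names(conditions)[conditions == treated]
  correlations <- list()
  for (ids in list(ctrl_ids, trt_ids))
    if (length(ids) >= 2)
      correlations[[paste(ids[1], ids[2], sep = "_vs_")]] <-
        methylation_correlation(methylomes[[ids[1]]], methylomes[[ids[2]]])

  comparisons <- list()
  for (ci in ctrl_ids) for (ti in trt_ids) {
    nm <- paste(ci, ti, sep = "_vs_")
    comparisons[[nm]] <- stage(paste0("dmr:", nm),
      detect_dmrs(methylomes[[ci]], methylomes[[ti]], config$window,
                  config$min_sites, config$min_delta, config$p_threshold,
                  config$q_threshold, config$mode))
    write_dmrs(comparisons[[nm]],
               file.path(config$out_dir, sprintf("dmr_%s.tsv", nm)))
  }
  consensus <- stage("consensus", intersect_and_merge(comparisons))
  write.table(consensus, file.path(config$out_dir, "consensus_dmrs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$windows_tested <-
    vapply(comparisons, function(d) nrow(d$windows), 0L)
  manifest$counts$dmrs <- vapply(comparisons, function(d) nrow(d$dmrs), 0L)
  manifest$counts$consensus_dmrs <- nrow(consensus)

  top_matrix <- NULL
  if (nrow(consensus) > 0) {
    top_matrix <- stage("top-matrix",
                        top_dmr_matrix(consensus, methylomes, config$top_n))
    write.table(cbind(dmr = rownames(top_matrix), as.data.frame(top_matrix)),
                file.path(config$out_dir, "top_dmr_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  categories <- NULL; gene_map <- NULL; overlaps <- list()
  if (!is.null(genes) && nrow(consensus) > 0) {
    categories <- stage("annotate",
                        category_distribution(consensus, genes,
                                              config$promoter_flank))
    gene_map <- map_dmrs_to_genes(consensus, genes, config$promoter_flank)
    write.table(gene_map, file.path(config$out_dir, "dmr_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dmr_genes <- unique(gene_map$gene_id)
    universe <- nrow(genes$genes)
    for (nm in c("expression_genes", "splicing_genes")) {
      if (is.null(config[[nm]])) next
      ref <- read_gene_list(config[[nm]])
      overlaps[[sub("_genes", "", nm)]] <-
        overlap_stats(dmr_genes, ref, universe)
    }
  }

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  run <- structure(list(manifest = manifest, config = config,
                        genome = genome, fragments = fragments,
                        islands = islands, genes = genes,
                        truth = methylome_truth, read_truth = truths,
                        conditions = conditions,
                        methylomes = methylomes, qc = qc,
                        profile = profile, features = features,
                        correlations = correlations,
                        comparisons = comparisons, consensus = consensus,
                        top_matrix = top_matrix, categories = categories,
                        gene_map = gene_map, overlaps = overlaps),
                   class = "rrbs_run")
  write_report(run)
  write_manifest()
  invisible(run)
}

#' @export
print.rrbs_run <- function(x, ...) {
  cat(sprintf("rrbs_run: %d samples, %d fragments, %d consensus DMRs (%s)\n",
              length(x$methylomes), nrow(x$fragments), nrow(x$consensus),
              x$manifest$status))
  invisible(x)
}

#' Write the human-readable report and machine-readable summary
#'
#' Produces `report.md` (tabular analogs of the chromosome profile, feature
#' averages, replicate correlation, DMR category distribution and top-DMR
#' matrix) and `summary.json` with every summary number. Missing summaries
#' are listed as absent.
#'
#' @param run An `rrbs_run` from [run_pipeline()].
#' @param dir Output directory (defaults to the run's).
#' @return Invisibly, the report path.
#' @export
write_report <- function(run, dir = run$config$out_dir) {
  fmt_tab <- function(df) {
    if (is.null(df) || nrow(df) == 0) return("(absent)")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"), ""))
  }
  lines <- c("# RRBS pipeline report", "",
             sprintf("Samples: %s", paste(names(run$methylomes),
                                          collapse = ", ")), "",
             "## QC", "")
  for (sm in names(run$qc)) {
    q <- run$qc[[sm]]
    lines <- c(lines, sprintf(
      "- %s: conversion %.4f [%.4f, %.4f], mean CpG coverage %.2f, pass: %s",
      sm, q$conversion$rate, q$conversion$ci_low, q$conversion$ci_high,
      q$mean_cpg_coverage, q$pass))
  }
  lines <- c(lines, "", "## Replicate correlation (CpG levels)", "")
  if (length(run$correlations)) {
    for (nm in names(run$correlations))
      lines <- c(lines, sprintf("- %s: Pearson r = %.4f (n = %d)", nm,
                                run$correlations[[nm]]$r,
                                run$correlations[[nm]]$n_shared))
  } else lines <- c(lines, "(absent)")
  lines <- c(lines, "", "## Chromosome profile", "", fmt_tab(run$profile),
             "", "## Feature-class averages", "", fmt_tab(run$features),
             "", "## Consensus DMRs", "",
             sprintf("%d consensus DMRs from %d pairwise comparisons.",
                     nrow(run$consensus), length(run$comparisons)),
             "", fmt_tab(utils::head(run$consensus, 20)))
  if (!is.null(run$categories)) {
    f <- run$categories$fractions
    cnt <- run$categories$counts
    lines <- c(lines, "", "## DMR category distribution", "",
               sprintf("- %s: %.1f%% (%d)", names(f), 100 * f, cnt),
               sprintf("- sum check: %.6f", sum(f)))
  }
  if (!is.null(run$top_matrix))
    lines <- c(lines, "", "## Top DMR matrix", "",
               sprintf("%d DMRs x %d samples (see top_dmr_matrix.tsv)",
                       nrow(run$top_matrix), ncol(run$top_matrix)))
  if (length(run$overlaps)) {
    lines <- c(lines, "", "## Gene-list overlaps", "")
    for (nm in names(run$overlaps)) {
      o <- run$overlaps[[nm]]
      lines <- c(lines, sprintf(
        "- %s: %d/%d query genes overlap (%.1f%%), hypergeometric p = %.3g",
        nm, o$n_overlap, o$n_query, 100 * o$fraction, o$p))
    }
  }
  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  summary <- list(qc = run$qc,
                  correlations = run$correlations,
                  chromosome_profile = run$profile,
                  feature_averages = run$features,
                  n_consensus_dmrs = nrow(run$consensus),
                  categories = run$categories,
                  overlaps = run$overlaps)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
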