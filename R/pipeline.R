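#' Configuration for a full pipeline run
#'
#' Bundles the analysis constants — the 500-nt database extension, the 24-nt
#' cluster window, the 10-tag comparison gate, the 5-tpm expression filter,
#' the +1 pseudocount and the fold-change cutoff 2 — with either a synthetic
#' experiment ([pat_sim_config()]) or paths to real inputs.
#'
#' @param mode `"synthetic"` (generate reads from a simulated reference) or
#'   `"files"` (read FASTQ/FASTA/GFF3 inputs from disk).
#' @param sim A [pat_sim_config()] (synthetic mode).
#' @param reads,genome,annotation Input paths (files mode): multiplexed
#'   FASTQ, genome FASTA, 3'-UTR GFF3/BED.
#' @param barcodes Barcode tibble (`sample`, `genotype`, `barcode`) or a TSV
#'   path (files mode; synthetic mode takes it from `sim`).
#' @param bins Optional gene-to-bin tibble (`gene_id`, `bin_id`) or TSV path
#'   for functional-bin enrichment.
#' @param extension,cluster_window,min_tags,tpm_threshold,pseudocount,
#'   fold_cutoff,screen_low,screen_high,max_barcode_mismatch,max_map_mismatch,
#'   min_tag_length Stage parameters (see the stage functions).
#' @param seed Integer seed driving every stochastic stage.
#' @param output_dir Optional directory for exported tables.
#' @return A list of class `"pat_pipeline_config"`.
#' @export
pat_pipeline_config <- function(mode = c("synthetic", "files"),
                                sim = pat_sim_config(),
                                reads = NULL, genome = NULL,
                                annotation = NULL, barcodes = NULL,
                                bins = NULL,
                                extension = 500, cluster_window = 24,
                                min_tags = 10, tpm_threshold = 5,
                                pseudocount = 1, fold_cutoff = 2,
                                screen_low = 0.2, screen_high = 0.5,
                                max_barcode_mismatch = 0,
                                max_map_mismatch = 2, min_tag_length = 20,
                                seed = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    for (p in c(reads, genome, annotation)) {
      if (is.null(p) || !file.exists(p)) stop("missing input file: ", p)
    }
    if (is.character(barcodes)) barcodes <- readr::read_tsv(barcodes,
                                                            show_col_types = FALSE)
    if (is.null(barcodes)) stop("files mode needs a barcode table")
  } else {
    barcodes <- sim$barcode_table
  }
  if (is.character(bins)) bins <- readr::read_tsv(bins, show_col_types = FALSE)
  structure(list(
    mode = mode, sim = sim, reads = reads, genome = genome,
    annotation = annotation, barcodes = barcodes, bins = bins,
    extension = extension, cluster_window = cluster_window,
    min_tags = min_tags, tpm_threshold = tpm_threshold,
    pseudocount = pseudocount, fold_cutoff = fold_cutoff,
    screen_low = screen_low, screen_high = screen_high,
    max_barcode_mismatch = max_barcode_mismatch,
    max_map_mismatch = max_map_mismatch, min_tag_length = min_tag_length,
    seed = as.integer(seed %||% sim$seed), output_dir = output_dir
  ), class = "pat_pipeline_config")
}

#' Run the full PAT-seq analysis pipeline
#'
#' Chains simulate (or load), demultiplex, trim, database construction,
#' mapping, site profiling, all pairwise profile comparisons with cumulative
#' curves and the poly(A)-pattern screen, and the digital-expression branch
#' (tpm, expression filter, six log2 ratios, the calmodulin-dependence
#' filter, optional bin enrichment, and the proportions test on the wild
#' type versus mutant). Deterministic given the configuration seed. Any
#' stage failure propagates with the stage named in the error.
#'
#' @param config A [pat_pipeline_config()].
#' @param output_dir Directory for exported tables (FASTA/GFF3/FASTQ/SAM/TSV);
#'   `NULL` (default: the config's) keeps everything in memory.
#' @param quiet Suppress progress messages.
#' @return A list of class `"pat_run"`: `reference` (synthetic mode),
#'   `reads`, `demux`, `trimmed`, `db`, `hits`, `profiles`, `comparisons`,
#'   `curves`, `screen`, `expression` (list with `counts`, `tpm`,
#'   `filtered`, `ratios`, `cam_filter`, `bin_enrichment`, `proportions`),
#'   and `log`, a tibble of per-stage counts.
#' @export
run_pat_pipeline <- function(config = pat_pipeline_config(),
                             output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pat_pipeline_config"))
  output_dir <- output_dir %||% config$output_dir
  log <- list()
  note <- function(stage, metric, value) {
    if (!quiet) message(sprintf("[%s] %s = %s", stage, metric, value))
    log[[length(log) + 1]] <<- tibble(stage = stage, metric = metric,
                                      value = as.numeric(value))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  reference <- NULL
  if (config$mode == "synthetic") {
    reference <- stage("simulate", generate_reference(config$sim))
    sim <- stage("simulate", simulate_tag_reads(reference))
    reads <- sim$reads
    genome <- reference$genome
    annotation <- reference$annotation
  } else {
    reads <- stage("load", read_fastq(config$reads))
    genome <- stage("load", read_genome_fasta(config$genome))
    annotation <- stage("load", read_utr_annotation(config$annotation))
    sim <- NULL
  }
  note("reads", "total", nrow(reads))

  demuxed <- stage("demux", demultiplex(reads, config$barcodes,
                                        config$max_barcode_mismatch))
  assigned <- dplyr::filter(demuxed, .data$sample != "unassigned")
  note("demux", "assigned", nrow(assigned))
  note("demux", "unassigned", nrow(demuxed) - nrow(assigned))

  sim_cfg <- if (config$mode == "synthetic") config$sim else NULL
  trimmed <- stage("trim", trim_tags(
    assigned,
    adapter_5p = sim_cfg$adapter_5p %||% "AGCTGACT",
    adapter_3p = sim_cfg$adapter_3p %||% "AGATCGGAAGAGC",
    min_len = config$min_tag_length))
  note("trim", "trimmed", sum(trimmed$status == "trimmed"))
  note("trim", "discarded", sum(trimmed$status == "discarded"))

  db <- stage("makedb", build_extended_utr_db(annotation, genome,
                                              config$extension))
  note("makedb", "records", nrow(db))

  hits <- stage("map", map_tags(trimmed, db,
                                max_mismatch = config$max_map_mismatch))
  for (s in c("mapped", "unmapped", "multimapped")) {
    note("map", s, sum(hits$map_status == s))
  }

  profiles <- stage("profile", build_site_profiles(hits, config$cluster_window))
  note("profile", "genes", dplyr::n_distinct(profiles$gene_id))

  comparisons <- stage("apacompare", compare_all_pairs(
    profiles, min_tags = config$min_tags, window = config$cluster_window))
  note("apacompare", "comparisons", dplyr::n_distinct(comparisons$comparison))
  curves <- stage("apacompare", comparison_curves(comparisons))
  screen <- NULL
  if (all(pat_genotypes() %in% unique(profiles$sample))) {
    screen <- stage("apacompare", screen_pattern_genes(
      comparisons, config$screen_low, config$screen_high))
    note("apacompare", "screen_hits", nrow(screen))
  }

  counts <- stage("express", {
    hits |>
      dplyr::filter(.data$map_status == "mapped") |>
      dplyr::count(.data$gene_id, .data$sample, name = "count")
  })
  tpm <- stage("express", counts_to_tpm(counts))
  filtered <- stage("express", filter_expressed(tpm, config$tpm_threshold))
  note("express", "genes_expressed", dplyr::n_distinct(filtered$gene_id))

  ratios <- cam <- enrich <- props <- NULL
  if (all(pat_genotypes() %in% unique(filtered$sample))) {
    ratios <- stage("express", log2_ratio_matrix(
      filtered, pseudocount = config$pseudocount))
    cam <- stage("express", cam_dependent_filter(ratios, config$fold_cutoff))
    note("express", "cam_filter_pass", sum(cam$pass))
    if (!is.null(config$bins)) {
      wt_mut <- dplyr::filter(ratios, .data$comparison == "wt/oxt6")
      enrich <- stage("express", wilcoxon_bin_test(wt_mut, config$bins))
    }
    cw <- tidyr::pivot_wider(dplyr::select(filtered, "gene_id", "sample",
                                           "count"),
                             names_from = "sample", values_from = "count",
                             values_fill = 0L)
    lib <- dplyr::summarise(dplyr::group_by(counts, .data$sample),
                            n = sum(.data$count))
    libs <- setNames(lib$n, lib$sample)
    props <- stage("express", dplyr::mutate(
      baggerly_proportions_test(as.matrix(cw["wt"]), libs["wt"],
                                as.matrix(cw["oxt6"]), libs["oxt6"]),
      gene_id = cw$gene_id, .before = 1))
  }

  run <- structure(list(
    config = config, reference = reference, reads = reads,
    demux = demux_report(demuxed), trimmed = trimmed, db = db, hits = hits,
    profiles = profiles, comparisons = comparisons, curves = curves,
    screen = screen,
    expression = list(counts = counts, tpm = tpm, filtered = filtered,
                      ratios = ratios, cam_filter = cam,
                      bin_enrichment = enrich, proportions = props),
    log = dplyr::bind_rows(log)
  ), class = "pat_run")

  if (!is.null(output_dir)) stage("report", write_run(run, output_dir))
  run
}

#' Export a pipeline run to a directory of standard-format files
#'
#' Writes the genome FASTA, annotation (GFF3 and BED), multiplexed and
#' per-sample FASTQ, demultiplex report, database FASTA with coordinate map,
#' SAM alignments, profile/comparison/ECDF/expression/screen TSVs and the
#' run log.
#'
#' @param run A `"pat_run"` from [run_pat_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  if (!is.null(run$reference)) {
    write_genome_fasta(run$reference$genome, p("genome.fasta"))
    write_utr_annotation(run$reference$annotation, p("annotation.gff3"), "gff3")
    write_utr_annotation(run$reference$annotation, p("annotation.bed"), "bed")
    truth <- run$reference$truth
    readr::write_tsv(truth$genes, p("truth_genes.tsv"))
    readr::write_tsv(truth$sites, p("truth_sites.tsv"))
    readr::write_tsv(truth$usage, p("truth_usage.tsv"))
    readr::write_tsv(truth$expression, p("truth_expression.tsv"))
  }
  write_fastq(run$reads, p("reads.fastq"))
  readr::write_tsv(run$demux, p("demux_report.tsv"))
  for (s in setdiff(unique(run$trimmed$sample), "unassigned")) {
    keep <- dplyr::filter(run$trimmed, .data$sample == s,
                          .data$status == "trimmed")
    write_fastq(keep, p(paste0("tags_", s, ".fastq")))
  }
  write_utr_db(run$db, p("db.fasta"), p("db_map.tsv"))
  write_sam(run$hits, run$db, p("alignments.sam"))
  readr::write_tsv(run$profiles, p("site_profiles.tsv"))
  for (cmp in unique(run$comparisons$comparison)) {
    readr::write_tsv(
      dplyr::filter(as_tibble(run$comparisons), .data$comparison == cmp),
      p(paste0("comparison_", gsub("-", "_vs_", cmp), ".tsv")))
  }
  readr::write_tsv(run$curves, p("cumulative_curves.tsv"))
  if (!is.null(run$screen)) readr::write_tsv(run$screen, p("screen_genes.tsv"))
  readr::write_tsv(run$expression$tpm, p("expression_tpm.tsv"))
  if (!is.null(run$expression$ratios)) {
    readr::write_tsv(run$expression$ratios, p("expression_ratios.tsv"))
    readr::write_tsv(run$expression$cam_filter, p("cam_filter.tsv"))
  }
  if (!is.null(run$expression$bin_enrichment)) {
    readr::write_tsv(run$expression$bin_enrichment, p("bin_enrichment.tsv"))
  }
  if (!is.null(run$expression$proportions)) {
    readr::write_tsv(run$expression$proportions, p("proportions_test.tsv"))
  }
  readr::write_tsv(run$log, p("run_log.tsv"))
  invisible(dir)
}
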