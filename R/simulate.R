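#' Configuration for the synthetic PAT-seq experiment
#'
#' Defines the study conditions emulated by the generator: a small genome with
#' uniformly spaced genes on both strands, four barcoded samples (wild type,
#' the CPSF30-null mutant `oxt6`, and the complemented lines `C30G` and
#' `C30GM`), genotype-specific per-gene poly(A)-site usage in which `oxt6` is
#' shifted while both complemented lines are restored to wild type, and
#' genotype-specific expression levels including a planted minority of
#' calmodulin-dependent genes (`wt ~ C30G` differing `cam_fold`-fold from
#' `oxt6 ~ C30GM`, in either direction).
#'
#' @param n_chromosomes,genes_per_chromosome Genome layout (defaults 2 x 250).
#' @param utr_length_range Inclusive range of 3'-UTR lengths in nt.
#' @param n_sites_per_gene Inclusive range for the number of true poly(A)
#'   sites per gene.
#' @param cluster_sigma Standard deviation (nt) of the discretized Gaussian
#'   cleavage microheterogeneity around each true site (default 3).
#' @param depth_per_sample Expected total tag count per sample.
#' @param barcode_table Tibble with columns `sample`, `genotype`, `barcode`
#'   (pairwise distinct, equal-length barcodes). Extra rows give biological
#'   replicates of a genotype.
#' @param adapter_5p,adapter_3p Adapter sequences flanking the tag.
#' @param polyA_remnant_length_range Inclusive range of the A-run length
#'   between tag and 3' adapter.
#' @param tag_length Tag length in nt (default 50).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param extension Downstream extension used for site placement and mapping
#'   (default 500 nt).
#' @param planted_apa_fraction Fraction of genes whose `oxt6` usage vector is
#'   shifted while `wt`, `C30G` and `C30GM` are identical (default 0.10).
#' @param planted_cam_fraction Fraction of genes with calmodulin-dependent
#'   expression (default 0.02).
#' @param planted_screen_fraction Fraction of genes where `C30GM` *retains*
#'   the shifted `oxt6` usage (default 0; used to exercise the pattern
#'   screen, disjoint from the `planted_apa` class).
#' @param cam_fold Expression fold change planted in calmodulin-dependent
#'   genes (default 5).
#' @param seed Integer seed; all generator output is deterministic given the
#'   configuration and seed.
#' @return A validated list of class `"pat_sim_config"`.
#' @export
pat_sim_config <- function(n_chromosomes = 2,
                           genes_per_chromosome = 250,
                           utr_length_range = c(150, 400),
                           n_sites_per_gene = c(1, 3),
                           cluster_sigma = 3,
                           depth_per_sample = 2e5,
                           barcode_table = NULL,
                           adapter_5p = "AGCTGACT",
                           adapter_3p = "AGATCGGAAGAGC",
                           polyA_remnant_length_range = c(6, 12),
                           tag_length = 50,
                           error_rate = 0.002,
                           extension = 500,
                           planted_apa_fraction = 0.10,
                           planted_cam_fraction = 0.02,
                           planted_screen_fraction = 0,
                           cam_fold = 5,
                           seed = 1) {
  if (is.null(barcode_table)) {
    barcode_table <- tibble(
      sample = pat_genotypes(),
      genotype = pat_genotypes(),
      barcode = c("ACGTAC", "TGCAGT", "GATCGA", "CTAGCT")
    )
  }
  cfg <- list(
    n_chromosomes = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    utr_length_range = utr_length_range,
    n_sites_per_gene = n_sites_per_gene,
    cluster_sigma = cluster_sigma,
    depth_per_sample = depth_per_sample,
    barcode_table = barcode_table,
    adapter_5p = adapter_5p,
    adapter_3p = adapter_3p,
    polyA_remnant_length_range = polyA_remnant_length_range,
    tag_length = tag_length,
    error_rate = error_rate,
    extension = extension,
    planted_apa_fraction = planted_apa_fraction,
    planted_cam_fraction = planted_cam_fraction,
    planted_screen_fraction = planted_screen_fraction,
    cam_fold = cam_fold,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "pat_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_chromosomes, cfg$genes_per_chromosome, cfg$cluster_sigma,
              cfg$depth_per_sample, cfg$tag_length, cfg$extension)
  if (any(counts <= 0)) stop("all counts in the configuration must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) stop("error_rate must be in [0, 1)")
  props <- c(cfg$planted_apa_fraction, cfg$planted_cam_fraction,
             cfg$planted_screen_fraction)
  if (any(props < 0 | props > 1)) stop("planted fractions must be in [0, 1]")
  bt <- cfg$barcode_table
  if (!all(c("sample", "genotype", "barcode") %in% names(bt))) {
    stop("barcode_table needs columns sample, genotype, barcode")
  }
  if (anyDuplicated(bt$barcode)) stop("barcodes must be pairwise distinct")
  if (length(unique(nchar(bt$barcode))) != 1) stop("barcodes must be equal length")
  if (!all(bt$genotype %in% pat_genotypes())) {
    stop("genotypes must be among: ", paste(pat_genotypes(), collapse = ", "))
  }
  if (diff(cfg$utr_length_range) < 0 || cfg$utr_length_range[1] < 60) {
    stop("utr_length_range must be increasing with minimum >= 60")
  }
  if (cfg$n_sites_per_gene[1] < 1) stop("n_sites_per_gene must be >= 1")
  if ((cfg$planted_apa_fraction > 0 || cfg$planted_screen_fraction > 0) &&
      cfg$n_sites_per_gene[2] < 2) {
    stop("planted shifted genes require n_sites_per_gene max >= 2")
  }
  if (cfg$cam_fold <= 1) stop("cam_fold must exceed 1")
  invisible(cfg)
}

# uniform draw from an inclusive integer range, safe against R's
# sample(x) scalar collapse when lo == hi
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# n positions in [lo, hi] with pairwise spacing >= gap, uniform given the
# constraint (shift-and-spread construction, no rejection loop)
sample_spaced <- function(lo, hi, n, gap) {
  span <- hi - lo - (n - 1) * gap
  if (span < 0) stop("interval too small for ", n, " spaced sites")
  sort(sample.int(span + 1, n)) - 1 + lo + (seq_len(n) - 1) * gap
}

# concentrated usage vector: proportion `major` on site `major_site`,
# remainder spread equally
concentrated_usage <- function(n_sites, major_site, major) {
  v <- rep((1 - major) / (n_sites - 1), n_sites)
  v[major_site] <- major
  v
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Builds random chromosome sequences with non-overlapping gene slots on
#' alternating strands, places 1-3 true poly(A) sites per gene inside the
#' 3'-UTR or within the downstream extension (at least 60 nt apart so site
#' clusters stay resolvable), and draws per-genotype usage vectors and
#' expression means. Planted APA-shifted genes have identical usage in `wt`,
#' `C30G` and `C30GM` and a distinct vector in `oxt6`; planted
#' calmodulin-dependent genes have `cam_fold`-separated expression with the
#' `wt ~ C30G` vs `oxt6 ~ C30GM` pattern. Output is deterministic given the
#' configuration (including its seed).
#'
#' @param config A [pat_sim_config()].
#' @return A list of class `"pat_reference"` with elements `genome` (named
#'   character vector), `annotation` (UTR tibble, 0-based half-open),
#'   `truth` (list of tibbles `genes`, `sites`, `usage`, `expression`) and
#'   `config`.
#' @export
generate_reference <- function(config = pat_sim_config()) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    utr_max <- cfg$utr_length_range[2]
    slot <- utr_max + cfg$extension + 200
    chrom_len <- cfg$genes_per_chromosome * slot + 200
    if (chrom_len <= utr_max) stop("UTR longer than chromosome")
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    genome <- setNames(vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    }, character(1)), chroms)

    n_genes <- cfg$n_chromosomes * cfg$genes_per_chromosome
    gene_id <- sprintf("GENE%04d", seq_len(n_genes))
    chrom <- rep(chroms, each = cfg$genes_per_chromosome)
    slot_idx <- rep(seq_len(cfg$genes_per_chromosome), cfg$n_chromosomes)
    s0 <- (slot_idx - 1) * slot + 100
    strand <- rep_len(c("+", "-"), n_genes)
    utr_len <- sample_range(cfg$utr_length_range[1], cfg$utr_length_range[2],
                            n_genes)
    start <- ifelse(strand == "+", s0, s0 + cfg$extension)
    end <- start + utr_len
    annotation <- tibble(gene_id = gene_id, chrom = chrom,
                         start = start, end = end, strand = strand)

    # planted classes (screen genes are drawn outside the APA-shifted class)
    n_apa <- round(cfg$planted_apa_fraction * n_genes)
    n_cam <- round(cfg$planted_cam_fraction * n_genes)
    n_scr <- round(cfg$planted_screen_fraction * n_genes)
    apa_genes <- sample(gene_id, n_apa)
    scr_genes <- sample(setdiff(gene_id, apa_genes), n_scr)
    cam_genes <- sample(gene_id, n_cam)
    shifted <- gene_id %in% c(apa_genes, scr_genes)

    n_sites <- sample_range(cfg$n_sites_per_gene[1], cfg$n_sites_per_gene[2],
                            n_genes)
    n_sites[shifted] <- pmax(n_sites[shifted], 2L)

    genes <- tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      utr_length = utr_len, n_sites = n_sites,
      planted_apa_shifted = gene_id %in% apa_genes,
      planted_cam_dependent = gene_id %in% cam_genes,
      planted_screen = gene_id %in% scr_genes
    )

    # true sites in database coordinates (0 = 3'-most base of the extension);
    # keep a full tag plus jitter inside the record
    db_len <- utr_len + cfg$extension
    lo <- rep(5 + 4 * cfg$cluster_sigma, n_genes)
    hi <- db_len - cfg$tag_length - 4 * cfg$cluster_sigma
    sites <- purrr::map_dfr(seq_len(n_genes), function(i) {
      pos <- sample_spaced(lo[i], hi[i], n_sites[i], gap = 60)
      tibble(gene_id = gene_id[i], site = seq_len(n_sites[i]), db_pos = pos)
    })
    span_start <- ifelse(strand == "+", start, start - cfg$extension)
    span_end <- ifelse(strand == "+", end + cfg$extension, end)
    si <- match(sites$gene_id, gene_id)
    sites$chrom <- chrom[si]
    sites$strand <- strand[si]
    sites$genomic_pos <- ifelse(strand[si] == "+",
                                span_end[si] - 1 - sites$db_pos,
                                span_start[si] + sites$db_pos)

    # usage vectors per genotype
    usage <- purrr::map_dfr(seq_len(n_genes), function(i) {
      k <- n_sites[i]
      if (shifted[i]) {
        major <- runif(1, 0.75, 0.9)
        wt <- concentrated_usage(k, 1L, major)
        mut <- concentrated_usage(k, 2L, major)
        retained <- gene_id[i] %in% scr_genes
        vecs <- list(wt = wt, oxt6 = mut, C30G = wt,
                     C30GM = if (retained) mut else wt)
      } else {
        v <- rgamma(k, shape = 1)
        v <- v / sum(v)
        vecs <- list(wt = v, oxt6 = v, C30G = v, C30GM = v)
      }
      tibble(gene_id = gene_id[i],
             site = rep(seq_len(k), times = 4),
             genotype = rep(pat_genotypes(), each = k),
             usage = unlist(vecs, use.names = FALSE))
    })

    # expression: log-uniform base weights, calmodulin-dependent genes get a
    # cam_fold drop in oxt6/C30GM (or in wt/C30G, direction drawn per gene);
    # per-genotype means are scaled so each genotype totals depth_per_sample
    w <- exp(runif(n_genes, log(1), log(5)))
    mult <- matrix(1, nrow = n_genes, ncol = 4,
                   dimnames = list(gene_id, pat_genotypes()))
    cam_idx <- which(gene_id %in% cam_genes)
    # planted expression patterns sit on solidly expressed genes, so the
    # planted fold (not counting noise) dominates their ratios
    w[cam_idx] <- exp(runif(length(cam_idx), log(2.5), log(5)))
    up_in_wt <- runif(length(cam_idx)) < 0.5
    mult[cam_idx[up_in_wt], c("oxt6", "C30GM")] <- 1 / cfg$cam_fold
    mult[cam_idx[!up_in_wt], c("wt", "C30G")] <- 1 / cfg$cam_fold
    expression <- purrr::map_dfr(pat_genotypes(), function(g) {
      m <- w * mult[, g]
      tibble(gene_id = gene_id, genotype = g,
             mean_count = cfg$depth_per_sample * m / sum(m))
    })

    structure(
      list(genome = genome, annotation = annotation,
           truth = list(genes = genes, sites = sites,
                        usage = usage, expression = expression),
           config = cfg),
      class = "pat_reference"
    )
  })
}

#' Draw per-gene tag counts from the generator truth
#'
#' Counts are Poisson around the genotype expression means (the simplest
#' noise model consistent with tag counting; swap in an overdispersed draw by
#' sampling from `truth$expression` yourself if needed).
#'
#' @param reference A `"pat_reference"` from [generate_reference()].
#' @param samples Tibble with columns `sample` and `genotype`; defaults to
#'   the configuration's barcode table.
#' @param seed Integer seed (default: the configuration seed plus 1).
#' @return Tibble with `gene_id`, `sample`, `genotype` and `count`.
#' @export
simulate_tag_counts <- function(reference, samples = NULL, seed = NULL) {
  cfg <- reference$config
  samples <- samples %||% cfg$barcode_table
  seed <- seed %||% (cfg$seed + 1L)
  expr <- reference$truth$expression
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(samples)), function(i) {
      g <- samples$genotype[i]
      e <- dplyr::filter(expr, .data$genotype == g)
      tibble(gene_id = e$gene_id, sample = samples$sample[i], genotype = g,
             count = rpois(nrow(e), e$mean_count))
    })
  })
}

#' Simulate multiplexed PAT-seq reads
#'
#' Emits one multiplexed read set covering all configured samples. Each read
#' is `barcode + 5' adapter + tag + poly(A) remnant + 3' adapter`; the tag is
#' the `tag_length` nt of mRNA-sense sequence ending at a cleavage position
#' drawn from the gene's genotype usage vector and jittered by a discretized
#' Gaussian of width `cluster_sigma` (truncated to the extended record).
#' Per-gene read counts are Poisson around the genotype expression means.
#' Substitution errors are applied uniformly at `error_rate` per base.
#' Output read order is shuffled and the whole result is deterministic given
#' the configuration and seed.
#'
#' @param reference A `"pat_reference"` from [generate_reference()].
#' @param seed Integer seed (default: the configuration seed plus 2).
#' @return A list of class `"pat_tag_sim"`: `reads` (tibble `read_id`,
#'   `sequence`, `quality`) and `read_info`, the per-read ground truth
#'   (`read_id`, `sample`, `genotype`, `gene_id`, `site`, `junction_db`,
#'   `chrom`, `junction_genomic`, `strand`).
#' @export
simulate_tag_reads <- function(reference, seed = NULL) {
  cfg <- reference$config
  seed <- seed %||% (cfg$seed + 2L)
  db <- build_extended_utr_db(reference$annotation, reference$genome,
                              extension = cfg$extension)
  sense_seq <- revcomp(db$db_seq)  # mRNA-sense extended records
  sites <- reference$truth$sites
  usage <- reference$truth$usage
  L <- cfg$tag_length
  bt <- cfg$barcode_table

  withr::with_seed(seed, {
    counts <- purrr::map_dfr(seq_len(nrow(bt)), function(i) {
      e <- dplyr::filter(reference$truth$expression,
                         .data$genotype == bt$genotype[i])
      tibble(gene_id = e$gene_id, sample = bt$sample[i],
             genotype = bt$genotype[i],
             count = rpois(nrow(e), e$mean_count))
    })
    counts <- dplyr::filter(counts, .data$count > 0)

    per_gene <- dplyr::left_join(
      counts,
      tidyr::nest(dplyr::select(sites, "gene_id", "site", "db_pos"),
                  .sites = c("site", "db_pos")),
      by = "gene_id"
    )
    usage_nested <- tidyr::nest(usage, .usage = c("site", "usage"))

    per_gene <- dplyr::left_join(per_gene, usage_nested,
                                 by = c("gene_id", "genotype"))
    drawn <- purrr::pmap_dfr(
      list(per_gene$gene_id, per_gene$sample, per_gene$genotype,
           per_gene$count, per_gene$.sites, per_gene$.usage),
      function(gid, smp, gt, n, st, us) {
        idx <- sample.int(nrow(st), n, replace = TRUE, prob = us$usage)
        tibble(gene_id = gid, sample = smp, genotype = gt,
               site = st$site[idx], site_db = st$db_pos[idx])
      })

    n_reads <- nrow(drawn)
    gi <- match(drawn$gene_id, db$gene_id)
    dblen <- db$db_length[gi]
    jitter <- as.integer(round(rnorm(n_reads, 0, cfg$cluster_sigma)))
    j <- pmin(pmax(drawn$site_db + jitter, 0L), dblen - L)

    tag <- substring(sense_seq[gi], dblen - j - L + 1, dblen - j)
    remnant <- strrep("A", sample_range(cfg$polyA_remnant_length_range[1],
                                        cfg$polyA_remnant_length_range[2],
                                        n_reads))
    bc <- setNames(bt$barcode, bt$sample)
    seqs <- paste0(bc[drawn$sample], cfg$adapter_5p, tag, remnant,
                   cfg$adapter_3p)
    seqs <- inject_substitutions(seqs, cfg$error_rate)

    ord <- sample.int(n_reads)
    read_id <- sprintf("tag%07d", seq_len(n_reads))
    plus <- db$strand[gi] == "+"
    junction_genomic <- ifelse(plus, db$span_end[gi] - 1 - j,
                               db$span_start[gi] + j)
    info <- tibble(
      read_id = read_id,
      sample = drawn$sample[ord], genotype = drawn$genotype[ord],
      gene_id = drawn$gene_id[ord], site = drawn$site[ord],
      junction_db = j[ord],
      chrom = db$chrom[gi][ord],
      junction_genomic = junction_genomic[ord],
      strand = db$strand[gi][ord]
    )
    reads <- tibble(read_id = read_id, sequence = seqs[ord],
                    quality = strrep("I", nchar(seqs[ord])))
    structure(list(reads = reads, read_info = info, config = cfg),
              class = "pat_tag_sim")
  })
}

# uniform per-base substitutions at rate p (draws nothing when p = 0)
inject_substitutions <- function(seqs, p) {
  if (p <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(seqs), nchar(seqs), p)
  for (i in which(n_err > 0L)) {
    s <- seqs[i]
    pos <- sample.int(nchar(s), n_err[i])
    for (pp in pos) {
      old <- substr(s, pp, pp)
      substr(s, pp, pp) <- sample(setdiff(bases, old), 1L)
    }
    seqs[i] <- s
  }
  seqs
}
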