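#' Per-gene poly(A)-profile difference metric
#'
#' The difference between two normalized usage vectors over a common set of
#' (matched) poly(A)-site clusters, `D = 0.5 * sum(|p_i - q_i|)` — the total
#' variation distance. `D` is 0 exactly when the profiles are identical and
#' attains its upper limit 1 exactly when the supports are disjoint; it is
#' symmetric, bounded in `[0, 1]` and satisfies the triangle inequality.
#'
#' @param p,q Non-negative usage vectors of equal length, each summing to 1
#'   (tolerance 1e-6). Build them over the union of the two samples' clusters
#'   with [genomewide_comparison()], which matches clusters across samples.
#' @return The difference metric, a single number in `[0, 1]`.
#' @export
#' @examples
#' profile_difference(c(0.75, 0.25), c(0.25, 0.75))  # 0.5
#' profile_difference(c(1, 0), c(0, 1))              # 1, the upper limit
profile_difference <- function(p, q) {
  if (length(p) != length(q) || length(p) == 0) {
    stop("p and q must be non-empty vectors of equal length")
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("usage vectors must be non-negative and sum to 1")
  }
  0.5 * sum(abs(p - q))
}

#' Genome-wide pairwise comparison of poly(A)-site profiles
#'
#' For every gene with at least `min_tags` mapped tags in *both* samples,
#' matches site clusters across the two samples (representatives within
#' `window` nt are merged by single linkage), renormalizes each sample's
#' usage over the merged clusters, and computes [profile_difference()].
#'
#' @param profiles Site-profile tibble from [build_site_profiles()].
#' @param sample_a,sample_b Sample labels present in `profiles`.
#' @param min_tags Minimum per-gene tag count required in both samples
#'   (default 10).
#' @param window Cross-sample cluster matching window in nt (default 24, the
#'   same scale as profile clustering).
#' @return Tibble with `gene_id`, `d` and the per-sample tag totals
#'   `n_a`, `n_b`. Empty (with a warning) if no gene passes the gate.
#' @export
genomewide_comparison <- function(profiles, sample_a, sample_b,
                                  min_tags = 10, window = 24) {
  pa <- dplyr::filter(profiles, .data$sample == sample_a)
  pb <- dplyr::filter(profiles, .data$sample == sample_b)
  tot_a <- dplyr::summarise(dplyr::group_by(pa, .data$gene_id),
                            n = sum(.data$count))
  tot_b <- dplyr::summarise(dplyr::group_by(pb, .data$gene_id),
                            n = sum(.data$count))
  keep <- dplyr::inner_join(
    dplyr::filter(tot_a, .data$n >= min_tags),
    dplyr::filter(tot_b, .data$n >= min_tags),
    by = "gene_id", suffix = c("_a", "_b"))
  if (nrow(keep) == 0) {
    warning("no gene has >= ", min_tags, " tags in both samples")
    return(tibble(gene_id = character(), d = double(),
                  n_a = integer(), n_b = integer()))
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(dplyr::semi_join(pa, keep, by = "gene_id"), .side = "a"),
    dplyr::mutate(dplyr::semi_join(pb, keep, by = "gene_id"), .side = "b"))
  both <- dplyr::arrange(both, .data$gene_id, .data$site)
  new_gene <- c(TRUE, both$gene_id[-1] != both$gene_id[-nrow(both)])
  gap <- c(0L, diff(both$site))
  both$cluster <- cumsum(new_gene | gap > window)
  d_tbl <- both |>
    dplyr::group_by(.data$gene_id, .data$cluster) |>
    dplyr::summarise(
      c_a = sum(.data$count[.data$.side == "a"]),
      c_b = sum(.data$count[.data$.side == "b"]), .groups = "drop_last") |>
    dplyr::summarise(
      d = 0.5 * sum(abs(.data$c_a / sum(.data$c_a) -
                        .data$c_b / sum(.data$c_b))),
      .groups = "drop")
  out <- dplyr::left_join(d_tbl, keep, by = "gene_id")
  tibble(gene_id = out$gene_id, d = out$d,
         n_a = out$n_a, n_b = out$n_b)
}

#' All pairwise profile comparisons of an experiment
#'
#' Runs [genomewide_comparison()] on every unordered pair of samples (or on
#' the pairs supplied) and stacks the results into a comparison set, the
#' object behind cumulative-curve plots and the poly(A)-pattern screen.
#'
#' @param profiles Site-profile tibble from [build_site_profiles()].
#' @param samples Character vector of sample labels (default: all samples in
#'   `profiles`, in order of appearance).
#' @param min_tags,window Passed to [genomewide_comparison()].
#' @return A tibble of class `"pat_comparison_set"` with columns `sample_a`,
#'   `sample_b`, `comparison`, `gene_id`, `d`, `n_a`, `n_b`.
#' @export
compare_all_pairs <- function(profiles, samples = NULL,
                              min_tags = 10, window = 24) {
  samples <- samples %||% unique(profiles$sample)
  if (length(samples) < 2) stop("need at least two samples")
  pairs <- utils::combn(samples, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dplyr::mutate(genomewide_comparison(profiles, a, b, min_tags, window),
                  sample_a = a, sample_b = b,
                  comparison = paste0(a, "-", b), .before = 1)
  })
  structure(out, class = c("pat_comparison_set", class(tibble())),
            min_tags = min_tags, window = window)
}

#' Cumulative curve of per-gene difference metrics
#'
#' The right-continuous empirical CDF of the observed `D` values: for each
#' threshold, the fraction of genes whose metric is at or below it. Curves
#' for similar samples rise early (left-shifted); genome-wide differences in
#' poly(A)-site choice push the curve right.
#'
#' @param d Numeric vector of per-gene difference metrics (at least one).
#' @param label Optional comparison label stored alongside.
#' @return Tibble with `threshold` (sorted observed values) and
#'   `cumulative_fraction`, reaching 1 at the maximum observed value; plus a
#'   `comparison` column when `label` is given.
#' @export
#' @examples
#' cumulative_curve(c(0.1, 0.2, 0.3))
cumulative_curve <- function(d, label = NULL) {
  if (length(d) == 0) stop("need at least one value")
  thr <- sort(unique(d))
  out <- tibble(threshold = thr,
                cumulative_fraction = vapply(thr, function(t) mean(d <= t),
                                             double(1)))
  if (!is.null(label)) out <- dplyr::mutate(out, comparison = label, .before = 1)
  out
}

#' Cumulative curves for every comparison in a set
#'
#' @param comparisons A `"pat_comparison_set"` from [compare_all_pairs()].
#' @return Stacked [cumulative_curve()] tibbles, one per comparison.
#' @export
comparison_curves <- function(comparisons) {
  comparisons |>
    as_tibble() |>
    dplyr::group_by(.data$comparison) |>
    dplyr::group_modify(~ cumulative_curve(.x$d)) |>
    dplyr::ungroup()
}

#' Screen for genes with calmodulin-dependent poly(A)-site choice
#'
#' Returns genes whose poly(A) profile is wild-type-like in the `rescue` line
#' but mutant-like in the `rescue_mutant` line: `D(wt, rescue) <= low_thr`,
#' `D(mutant, rescue_mutant) <= low_thr`, `D(wt, rescue_mutant) >= high_thr`
#' and `D(wt, mutant) >= high_thr`. Genes must pass the tag gate in all four
#' comparisons. When the rescue-mutant line fully restores wild-type site
#' choice the screen returns no genes.
#'
#' @param comparisons A `"pat_comparison_set"` covering the four genotypes.
#' @param low_thr Maximum metric for the "same profile" conditions
#'   (default 0.2).
#' @param high_thr Minimum metric for the "shifted profile" conditions
#'   (default 0.5); must exceed `low_thr`.
#' @param wt,mutant,rescue,rescue_mutant Sample labels (defaults `"wt"`,
#'   `"oxt6"`, `"C30G"`, `"C30GM"`).
#' @return Tibble of passing genes with the four metrics
#'   (`d_wt_rescue`, `d_mut_rescue_mut`, `d_wt_rescue_mut`, `d_wt_mut`).
#' @export
screen_pattern_genes <- function(comparisons, low_thr = 0.2, high_thr = 0.5,
                                 wt = "wt", mutant = "oxt6",
                                 rescue = "C30G", rescue_mutant = "C30GM") {
  if (low_thr >= high_thr) stop("low_thr must be smaller than high_thr")
  get_pair <- function(a, b) {
    x <- dplyr::filter(as_tibble(comparisons),
                       (.data$sample_a == a & .data$sample_b == b) |
                         (.data$sample_a == b & .data$sample_b == a))
    if (nrow(x) == 0) stop("comparison ", a, "-", b, " not present")
    dplyr::select(x, "gene_id", "d")
  }
  m <- get_pair(wt, rescue) |>
    dplyr::rename(d_wt_rescue = "d") |>
    dplyr::inner_join(dplyr::rename(get_pair(mutant, rescue_mutant),
                                    d_mut_rescue_mut = "d"), by = "gene_id") |>
    dplyr::inner_join(dplyr::rename(get_pair(wt, rescue_mutant),
                                    d_wt_rescue_mut = "d"), by = "gene_id") |>
    dplyr::inner_join(dplyr::rename(get_pair(wt, mutant),
                                    d_wt_mut = "d"), by = "gene_id")
  dplyr::filter(m, .data$d_wt_rescue <= low_thr,
                .data$d_mut_rescue_mut <= low_thr,
                .data$d_wt_rescue_mut >= high_thr,
                .data$d_wt_mut >= high_thr)
}
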