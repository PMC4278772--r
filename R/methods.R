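#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a comparison set
#'
#' @param x A `"pat_comparison_set"` from [compare_all_pairs()].
#' @param ... Unused.
#' @return One row per gene and comparison: `sample_a`, `sample_b`,
#'   `comparison`, `gene_id`, `d`, `n_a`, `n_b`.
#' @export
tidy.pat_comparison_set <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a comparison set
#'
#' @param x A `"pat_comparison_set"`.
#' @param ... Unused.
#' @return Tibble with `n_comparisons`, `n_genes` (distinct genes over all
#'   comparisons), `min_tags` and `window`.
#' @export
glance.pat_comparison_set <- function(x, ...) {
  tibble(n_comparisons = dplyr::n_distinct(x$comparison),
         n_genes = dplyr::n_distinct(x$gene_id),
         min_tags = attr(x, "min_tags"),
         window = attr(x, "window"))
}

#' Per-comparison summary of difference metrics
#'
#' @param comparisons A `"pat_comparison_set"`.
#' @return Tibble with per-comparison gene counts and mean/median metric.
#' @export
summarize_comparisons <- function(comparisons) {
  comparisons |>
    as_tibble() |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     mean_d = mean(.data$d),
                     median_d = stats::median(.data$d))
}

#' Superimposed cumulative curves of a comparison set
#'
#' The standard genome-wide view: one empirical CDF of the per-gene
#' difference metric per pairwise comparison. Left-shifted curves indicate
#' genome-wide similarity of poly(A)-site choice; right-shifted curves
#' indicate widespread differences.
#'
#' @param object A `"pat_comparison_set"` from [compare_all_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pat_comparison_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$d, colour = .data$comparison)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "poly(A) profile difference metric (D)",
                  y = "cumulative fraction of genes",
                  colour = "comparison") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pat_comparison_set
#' @param comparisons A `"pat_comparison_set"`.
#' @export
plot_comparison_curves <- function(comparisons, ...) {
  autoplot.pat_comparison_set(comparisons, ...)
}

#' Bar plot of functional-bin enrichment
#'
#' Plots each bin's `log10(1/p)` from [wilcoxon_bin_test()]; taller bars are
#' stronger departures of the bin's expression ratios from the background.
#'
#' @param enrichment Tibble from [wilcoxon_bin_test()].
#' @return A ggplot object.
#' @export
plot_bin_enrichment <- function(enrichment) {
  df <- dplyr::arrange(enrichment, dplyr::desc(.data$log10_inv_p))
  df$bin_id <- factor(df$bin_id, levels = df$bin_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_id, y = .data$log10_inv_p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "functional bin", y = "log10(1 / p)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
print.pat_run <- function(x, ...) {
  cat("<pat_run>\n")
  cat("  samples:", paste(setdiff(unique(x$trimmed$sample), "unassigned"),
                          collapse = ", "), "\n")
  cat("  reads:", nrow(x$reads), "| mapped:",
      sum(x$hits$map_status == "mapped"), "\n")
  cat("  genes profiled:", dplyr::n_distinct(x$profiles$gene_id), "\n")
  cat("  comparisons:", dplyr::n_distinct(x$comparisons$comparison), "\n")
  invisible(x)
}

#' @export
print.pat_sim_config <- function(x, ...) {
  cat("<pat_sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %d genes\n",
              x$n_chromosomes, x$genes_per_chromosome))
  cat(sprintf("  depth: %g tags/sample across %d samples\n",
              x$depth_per_sample, nrow(x$barcode_table)))
  cat(sprintf("  planted: %.0f%% APA-shifted, %.0f%% calmodulin-dependent (fold %g)\n",
              100 * x$planted_apa_fraction, 100 * x$planted_cam_fraction,
              x$cam_fold))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
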