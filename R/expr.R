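#' Convert tag counts to tags per million
#'
#' `tpm = count / sample_total * 1e6`, where the sample total is the sum of
#' the counts supplied, so each sample's tpm column sums to one million when
#' computed over all mapped tags.
#'
#' @param counts Long tibble with columns `gene_id`, `sample`, `count`.
#' @return The input with a `tpm` column added.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), sample = "s1",
#'                          count = c(10, 90))
#' counts_to_tpm(counts)$tpm  # 100000, 900000
counts_to_tpm <- function(counts) {
  stopifnot(all(c("gene_id", "sample", "count") %in% names(counts)))
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$sample),
                             total = sum(.data$count))
  if (any(totals$total <= 0)) {
    stop("sample with zero total count: ",
         paste(totals$sample[totals$total <= 0], collapse = ", "))
  }
  counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(tpm = .data$count / sum(.data$count) * 1e6) |>
    dplyr::ungroup()
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose tpm is *strictly greater than* `threshold` in at least
#' one sample; all other genes are removed. Raising the threshold can only
#' remove genes, never add them.
#'
#' @param tpm Tibble from [counts_to_tpm()] (long, with a `tpm` column).
#' @param threshold Expression threshold in tags per million (default 5).
#' @return The input tibble restricted to retained genes.
#' @export
filter_expressed <- function(tpm, threshold = 5) {
  stopifnot(threshold >= 0, "tpm" %in% names(tpm))
  keep <- tpm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(keep = any(.data$tpm > threshold)) |>
    dplyr::filter(.data$keep)
  dplyr::semi_join(tpm, keep, by = "gene_id")
}

#' Pairwise expression ratios on pseudocount-adjusted tpm
#'
#' For each comparison `"num/den"`, computes
#' `ratio = (tpm_num + pseudocount) / (tpm_den + pseudocount)` and its log2.
#' The pseudocount (default 1, added to each normalized expression value)
#' precludes division by zero; two unexpressed genes get ratio 1.
#'
#' @param tpm Long tibble with `gene_id`, `sample`, `tpm` (typically after
#'   [filter_expressed()]).
#' @param comparisons Character vector of `"numerator/denominator"` sample
#'   pairs; defaults to the six comparisons of the four-genotype design
#'   ([pat_default_comparisons()]).
#' @param pseudocount Positive value added to each tpm (default 1).
#' @return Tibble with `gene_id`, `comparison`, `ratio`, `log2_ratio`.
#' @export
#' @examples
#' tpm <- tibble::tibble(gene_id = "g1", sample = c("wt", "oxt6"),
#'                       tpm = c(31, 7))
#' log2_ratio_matrix(tpm, "wt/oxt6")  # ratio 4, log2 = 2
log2_ratio_matrix <- function(tpm, comparisons = pat_default_comparisons(),
                              pseudocount = 1) {
  stopifnot(pseudocount > 0)
  parts <- stringr::str_split_fixed(comparisons, stringr::fixed("/"), 2)
  missing <- setdiff(unique(c(parts)), unique(tpm$sample))
  if (length(missing) > 0) {
    stop("samples not present in tpm table: ", paste(missing, collapse = ", "))
  }
  wide <- tidyr::pivot_wider(dplyr::select(tpm, "gene_id", "sample", "tpm"),
                             names_from = "sample", values_from = "tpm")
  purrr::map_dfr(seq_along(comparisons), function(i) {
    r <- (wide[[parts[i, 1]]] + pseudocount) / (wide[[parts[i, 2]]] + pseudocount)
    tibble(gene_id = wide$gene_id, comparison = comparisons[i],
           ratio = r, log2_ratio = log2(r))
  })
}

#' Six-comparison screen for calmodulin-dependent expression
#'
#' A gene passes when its fold change exceeds `cutoff` in all four
#' discriminating comparisons and stays below `cutoff` in both control
#' comparisons. "Fold change" is the symmetric magnitude of the expression
#' ratio, `max(r, 1/r)` (ratios of positive adjusted tpm cannot be negative,
#' so the comparison `fold > cutoff` is the same as `|log2 r| > log2(cutoff)`).
#' With the default labels, the discriminating comparisons contrast the
#' intact-calmodulin-site backgrounds (`wt`, `C30G`) with the deficient ones
#' (`oxt6`, `C30GM`), and the controls compare within each class.
#'
#' @param ratios Tibble from [log2_ratio_matrix()] covering all six
#'   comparisons for every gene.
#' @param cutoff Fold-change cutoff (default 2).
#' @param discriminating,control Comparison labels for the two roles.
#' @return Tibble with one row per gene: the six fold changes (columns
#'   `fold_<comparison>` with `/` replaced by `_`) and a logical `pass`.
#' @export
cam_dependent_filter <- function(ratios, cutoff = 2,
                                 discriminating = c("wt/oxt6", "C30G/oxt6",
                                                    "wt/C30GM", "C30G/C30GM"),
                                 control = c("C30GM/oxt6", "wt/C30G")) {
  needed <- c(discriminating, control)
  have <- unique(ratios$comparison)
  if (length(setdiff(needed, have)) > 0) {
    stop("missing comparison: ", paste(setdiff(needed, have), collapse = ", "))
  }
  fold <- ratios |>
    dplyr::filter(.data$comparison %in% needed) |>
    dplyr::mutate(fold = pmax(.data$ratio, 1 / .data$ratio))
  incomplete <- fold |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n < length(needed))
  if (nrow(incomplete) > 0) {
    stop("missing comparison values for: ",
         paste(head(incomplete$gene_id, 5), collapse = ", "))
  }
  res <- fold |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pass = all(.data$fold[.data$comparison %in% discriminating] > cutoff) &&
        all(.data$fold[.data$comparison %in% control] < cutoff))
  wide <- fold |>
    dplyr::mutate(comparison = paste0(
      "fold_", stringr::str_replace_all(.data$comparison, "/", "_"))) |>
    dplyr::select("gene_id", "comparison", "fold") |>
    tidyr::pivot_wider(names_from = "comparison", values_from = "fold")
  dplyr::left_join(wide, res, by = "gene_id")
}

#' Wilcoxon rank-sum enrichment of functional bins
#'
#' Tests, for each functional bin, whether its member genes' log2 expression
#' ratios differ from those of all non-member genes (two-sided rank-sum
#' test). The exact null distribution is used when the smaller group has at
#' most `exact_max_n` members and there are no ties; otherwise the normal
#' approximation with average ranks and continuity correction. Uncorrected
#' p-values are reported together with `log10(1/p)`, the scale used for
#' plotting; a Benjamini-Hochberg adjusted column is appended as a
#' convenience and is not part of the original analysis.
#'
#' @param values Tibble with `gene_id` and the column named by `value_col`
#'   (default `"log2_ratio"`).
#' @param bins Tibble mapping `gene_id` to `bin_id` (many-to-many allowed).
#' @param value_col Name of the value column in `values`.
#' @param exact_max_n Largest small-group size for which the exact null is
#'   used (default 8).
#' @return Tibble with `bin_id`, `n_bin`, `n_background`, `statistic` (the
#'   rank-sum W of the bin), `p_value`, `log10_inv_p` and `p_adj_bh`. Bins
#'   with no member among `values`, or with an empty background, are skipped
#'   with a warning.
#' @export
wilcoxon_bin_test <- function(values, bins, value_col = "log2_ratio",
                              exact_max_n = 8) {
  stopifnot(value_col %in% names(values),
            all(c("gene_id", "bin_id") %in% names(bins)))
  v <- setNames(values[[value_col]], values$gene_id)
  out <- purrr::map_dfr(unique(bins$bin_id), function(b) {
    members <- intersect(bins$gene_id[bins$bin_id == b], names(v))
    x <- v[members]
    y <- v[setdiff(names(v), members)]
    if (length(x) == 0 || length(y) == 0) {
      warning("bin ", b, " skipped: empty bin or empty background")
      return(NULL)
    }
    exact <- min(length(x), length(y)) <= exact_max_n &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    # report the rank-sum W of the bin (U + its minimum rank sum)
    tibble(bin_id = b, n_bin = length(x), n_background = length(y),
           statistic = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
           p_value = wt$p.value,
           log10_inv_p = log10(1 / wt$p.value))
  })
  if (nrow(out) > 0) out$p_adj_bh <- p.adjust(out$p_value, method = "BH")
  out
}

#' Weighted proportions test for replicated count data
#'
#' Compares a gene's proportion of the library between two groups of
#' replicates with a weighted t-type statistic. Within each group the
#' per-replicate proportions `p_i = x_i / n_i` are combined with library-size
#' weights `w_i = n_i / N`; the variance of the weighted mean has a binomial
#' within-replicate component `p(1-p)/N` and a between-replicate
#' (overdispersion) component estimated from the weighted spread of the
#' `p_i` — the beta-binomial-style decomposition of the published test. The
#' two-sided p-value comes from a t distribution with
#' `(m_A - 1) + (m_B - 1)` degrees of freedom; with a single replicate per
#' group the between-replicate term is zero (there is nothing to estimate it
#' from) and the reference distribution is standard normal.
#'
#' @param x_a,x_b Gene counts: a vector (one gene, one entry per replicate)
#'   or a genes-by-replicates matrix.
#' @param n_a,n_b Positive library sizes, one per replicate.
#' @return Tibble with one row per gene: `proportion_a`, `proportion_b`,
#'   `statistic`, `df` and `p_value`. Swapping the groups negates the
#'   statistic and leaves the p-value unchanged.
#' @export
#' @examples
#' baggerly_proportions_test(c(1000, 1440), c(1e5, 1.2e5),
#'                           c(180, 330), c(9e4, 1.1e5))
baggerly_proportions_test <- function(x_a, n_a, x_b, n_b) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  xa <- as_mat(x_a); xb <- as_mat(x_b)
  if (length(n_a) != ncol(xa) || length(n_b) != ncol(xb)) {
    stop("library sizes must match the number of replicates")
  }
  if (any(n_a <= 0) || any(n_b <= 0)) stop("library sizes must be positive")
  if (nrow(xa) != nrow(xb)) stop("x_a and x_b must cover the same genes")

  group_moments <- function(x, n) {
    N <- sum(n)
    w <- n / N
    p_rep <- sweep(x, 2, n, "/")
    phat <- as.vector(x %*% rep(1, ncol(x))) / N
    vw <- phat * (1 - phat) / N
    if (ncol(x) > 1) {
      dev2 <- sweep(p_rep, 1, phat, "-")^2
      s2 <- as.vector(dev2 %*% w) / (1 - sum(w^2))
      vb <- s2 * sum(w^2)
    } else {
      vb <- 0
    }
    list(phat = phat, var = vw + vb)
  }
  a <- group_moments(xa, n_a)
  b <- group_moments(xb, n_b)
  se <- sqrt(a$var + b$var)
  stat <- ifelse(se > 0, (a$phat - b$phat) / se, 0)
  df <- (ncol(xa) - 1) + (ncol(xb) - 1)
  p <- if (df >= 1) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  tibble(proportion_a = a$phat, proportion_b = b$phat,
         statistic = stat, df = df, p_value = pmin(p, 1))
}
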