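test_that("tpm normalization scales each sample to one million", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), sample = "s1",
                           count = c(10, 90))
  expect_equal(counts_to_tpm(counts)$tpm, c(1e5, 9e5))

  eq <- tibble::tibble(gene_id = paste0("g", 1:8), sample = "s1", count = 3)
  expect_equal(counts_to_tpm(eq)$tpm, rep(1e6 / 8, 8))

  big <- withr::with_seed(2, tibble::tibble(
    gene_id = rep(paste0("g", 1:50), 2),
    sample = rep(c("a", "b"), each = 50),
    count = rpois(100, 40) + 1))
  tpm <- counts_to_tpm(big)
  sums <- tapply(tpm$tpm, tpm$sample, sum)
  expect_true(all(abs(sums - 1e6) < 1))  # 1e-6 relative
  expect_error(counts_to_tpm(tibble::tibble(gene_id = "g", sample = "s",
                                            count = 0)), "zero total")
})

test_that("the expression filter is strict and monotone in its threshold", {
  tpm <- tibble::tibble(
    gene_id = rep(c("edge", "one", "none"), each = 4),
    sample = rep(c("wt", "oxt6", "C30G", "C30GM"), 3),
    tpm = c(4.0, 4.9, 3.2, 5.0,   # never strictly above 5: removed
            0, 0, 5.1, 0,         # one sample above: retained
            1, 1, 1, 1))
  kept <- filter_expressed(tpm, threshold = 5)
  expect_equal(sort(unique(kept$gene_id)), "one")
  # threshold 0 keeps every gene with any expression
  kept0 <- filter_expressed(tpm, threshold = 0)
  expect_equal(sort(unique(kept0$gene_id)), c("edge", "none", "one"))
  # raising the threshold never adds genes
  for (thr in c(0, 1, 3, 5, 6)) {
    lo <- unique(filter_expressed(tpm, thr)$gene_id)
    hi <- unique(filter_expressed(tpm, thr + 1)$gene_id)
    expect_true(all(hi %in% lo))
  }
})

test_that("pseudocount-adjusted ratios and their log2 values are exact", {
  tpm <- tibble::tibble(gene_id = rep(c("g1", "g2", "g3"), each = 2),
                        sample = rep(c("wt", "oxt6"), 3),
                        tpm = c(31, 7, 12, 12, 0, 0))
  r <- log2_ratio_matrix(tpm, "wt/oxt6", pseudocount = 1)
  expect_equal(r$ratio, c(4, 1, 1))
  expect_equal(r$log2_ratio, c(2, 0, 0))
  expect_error(log2_ratio_matrix(tpm, "wt/missing"), "not present")
})

test_that("the six-comparison calmodulin filter follows the fold rules", {
  mk_ratios <- function(folds) {
    cmps <- pat_default_comparisons()
    tibble::tibble(gene_id = "g", comparison = cmps, ratio = folds,
                   log2_ratio = log2(folds))
  }
  pass <- mk_ratios(c(3, 2.5, 2.2, 2.1, 1.1, 1.2))
  expect_true(cam_dependent_filter(pass)$pass)
  # a discriminating comparison at fold 1.8 fails
  weak <- mk_ratios(c(3, 1.8, 2.2, 2.1, 1.1, 1.2))
  expect_false(cam_dependent_filter(weak)$pass)
  # a violated control comparison fails
  ctrl <- mk_ratios(c(3, 2.5, 2.2, 2.1, 1.1, 2.5))
  expect_false(cam_dependent_filter(ctrl)$pass)
  # fold change is symmetric: a 1/3 ratio counts as fold 3
  down <- mk_ratios(c(1 / 3, 1 / 2.5, 2.2, 2.1, 1.1, 1.2))
  expect_true(cam_dependent_filter(down)$pass)
  expect_error(cam_dependent_filter(pass[-1, ]), "missing comparison")
})

test_that("the bin rank-sum test equals exhaustive enumeration for small bins", {
  vals <- function(x, y) {
    tibble::tibble(gene_id = paste0("g", seq_along(c(x, y))),
                   log2_ratio = c(x, y))
  }
  bin_of <- function(x) tibble::tibble(gene_id = paste0("g", seq_along(x)),
                                       bin_id = "b")
  withr::with_seed(3, {
    cases <- list(
      list(x = c(1.2, 1.5, 0.9), y = c(-0.1, 0.05, 0.0, -0.2)),
      list(x = c(0.3, -1.2), y = c(0.1, 0.2, 0.25, -0.4, 0.9)),
      list(x = c(2.2, 0.4, -0.3, 0.8), y = c(0.5, -0.6, 1.4, 0.05, -1.1, 0.7)),
      list(x = rnorm(8), y = rnorm(9)))
    for (cs in cases) {
      got <- wilcoxon_bin_test(vals(cs$x, cs$y), bin_of(cs$x))
      expect_equal(got$p_value, perm_wilcox_p(cs$x, cs$y), tolerance = 1e-12)
      expect_equal(got$statistic, sum(rank(c(cs$x, cs$y))[seq_along(cs$x)]))
      expect_equal(got$log10_inv_p, log10(1 / got$p_value))
    }
  })
  # p = 0.01 plots as 2 on the log10(1/p) scale
  expect_equal(log10(1 / 0.01), 2)
})

test_that("bins with no members or no background are skipped with a warning", {
  v <- tibble::tibble(gene_id = c("g1", "g2"), log2_ratio = c(0.1, 0.4))
  empty <- tibble::tibble(gene_id = "gX", bin_id = "nobody")
  expect_warning(out <- wilcoxon_bin_test(v, empty), "skipped")
  expect_equal(nrow(out), 0)
  all_in <- tibble::tibble(gene_id = c("g1", "g2"), bin_id = "everyone")
  expect_warning(wilcoxon_bin_test(v, all_in), "skipped")
})

test_that("the proportions test matches an independently coded oracle", {
  # the two-replicate case: proportions A ~ (0.010, 0.012), B ~ (0.002, 0.003)
  xa <- c(1000, 1440); na <- c(1e5, 1.2e5)
  xb <- c(180, 330); nb <- c(9e4, 1.1e5)
  got <- baggerly_proportions_test(xa, na, xb, nb)
  want <- baggerly_oracle(xa, na, xb, nb)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  expect_equal(got$df, want$df)

  # a grid of replicate structures, including single replicates
  withr::with_seed(9, {
    for (i in 1:25) {
      ma <- sample(1:3, 1); mb <- sample(1:3, 1)
      na <- sample(5e4:2e5, ma); nb <- sample(5e4:2e5, mb)
      xa <- rpois(ma, na * 0.005); xb <- rpois(mb, nb * 0.004)
      got <- baggerly_proportions_test(xa, na, xb, nb)
      want <- baggerly_oracle(xa, na, xb, nb)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  })
})

test_that("the proportions test is antisymmetric and null at equality", {
  same <- baggerly_proportions_test(c(50, 60), c(1e4, 1.2e4),
                                    c(50, 60), c(1e4, 1.2e4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- baggerly_proportions_test(c(100, 140), c(1e4, 1.2e4),
                                 c(60, 50), c(9e3, 1.1e4))
  b <- baggerly_proportions_test(c(60, 50), c(9e3, 1.1e4),
                                 c(100, 140), c(1e4, 1.2e4))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)

  expect_error(baggerly_proportions_test(c(1, 2), c(100, 0), 1, 100),
               "positive")
})

test_that("gene matrices vectorize the proportions test row by row", {
  withr::with_seed(12, {
    xa <- matrix(rpois(10, 200), nrow = 5)
    xb <- matrix(rpois(10, 150), nrow = 5)
  })
  na <- c(5e4, 6e4); nb <- c(4e4, 7e4)
  got <- baggerly_proportions_test(xa, na, xb, nb)
  expect_equal(nrow(got), 5)
  for (i in 1:5) {
    want <- baggerly_oracle(xa[i, ], na, xb[i, ], nb)
    expect_equal(got$statistic[i], want$statistic, tolerance = 1e-10)
  }
})
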