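test_that("the profile difference metric matches its defining cases", {
  expect_equal(profile_difference(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(profile_difference(c(1, 0), c(0, 1)), 1.0)
  expect_equal(profile_difference(c(0.75, 0.25), c(0.25, 0.75)), 0.5)
  expect_error(profile_difference(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(profile_difference(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("the metric satisfies the metric axioms on random usage vectors", {
  withr::with_seed(5, {
    for (i in 1:300) {
      k <- sample(2:6, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      q <- rgamma(k, 1); q <- q / sum(q)
      r <- rgamma(k, 1); r <- r / sum(r)
      d_pq <- profile_difference(p, q)
      expect_gte(d_pq, 0); expect_lte(d_pq, 1)
      expect_equal(d_pq, profile_difference(q, p))
      expect_lte(d_pq,
                 profile_difference(p, r) + profile_difference(r, q) + 1e-12)
      expect_equal(profile_difference(p, p), 0)
    }
  })
})

test_that("genome-wide comparison gates on tags and matches clusters across samples", {
  profiles <- tibble::tibble(
    gene_id = c("low", "low", "hi", "hi", "hi"),
    sample = c("A", "B", "A", "A", "B"),
    site = c(100, 100, 100, 200, 110),
    count = c(5, 50, 30, 10, 40),
    usage = c(1, 1, 0.75, 0.25, 1))
  # 5 tags in one sample with min_tags 10: excluded
  cmp <- genomewide_comparison(profiles, "A", "B", min_tags = 10)
  expect_false("low" %in% cmp$gene_id)
  # sites 100 (A) and 110 (B) are within the 24-nt window: matched cluster,
  # so p = (0.75, 0.25) vs q = (1, 0) and D = 0.25
  expect_equal(cmp$d[cmp$gene_id == "hi"], 0.25)
  expect_warning(genomewide_comparison(profiles, "A", "B", min_tags = 1000),
                 "no gene")
})

test_that("a planted usage swap is recovered at its theoretical metric value", {
  # truth (0.8, 0.2) vs (0.2, 0.8): D = 0.6; multinomial sampling at depth
  # 1000 has sd(D-hat) ~ 0.018, so 0.08 covers > 4 sigma
  withr::with_seed(8, {
    ca <- as.vector(stats::rmultinom(1, 1000, c(0.8, 0.2)))
    cb <- as.vector(stats::rmultinom(1, 1000, c(0.2, 0.8)))
  })
  profiles <- tibble::tibble(
    gene_id = "g", sample = rep(c("A", "B"), each = 2),
    site = c(100, 200, 100, 200), count = c(ca, cb),
    usage = c(ca / sum(ca), cb / sum(cb)))
  d <- genomewide_comparison(profiles, "A", "B")$d
  expect_lt(abs(d - 0.6), 0.08)
})

test_that("replicate draws from identical truth give near-zero metrics", {
  ref <- generate_reference(tiny_config(seed = 51, planted_apa_fraction = 0))
  samples <- tibble::tibble(sample = c("r1", "r2"), genotype = "wt")
  prof <- profiles_from_truth(ref, samples, depth_factor = 3, seed = 2)
  cmp <- genomewide_comparison(prof, "r1", "r2")
  expect_lt(stats::median(cmp$d), 0.1)
})

test_that("cumulative curves are proper right-continuous ECDFs", {
  cc <- cumulative_curve(c(0.1, 0.2, 0.3))
  expect_equal(cc$cumulative_fraction[cc$threshold == 0.2], 2 / 3)
  # fraction at or below 0.25 equals the step value at 0.2
  expect_equal(max(cc$cumulative_fraction[cc$threshold <= 0.25]), 2 / 3)
  expect_equal(cc$cumulative_fraction[nrow(cc)], 1)
  zero <- cumulative_curve(rep(0, 5))
  expect_equal(zero$threshold, 0)
  expect_equal(zero$cumulative_fraction, 1)
  expect_true(all(diff(cc$cumulative_fraction) >= 0))
  expect_error(cumulative_curve(numeric(0)), "at least one")
})

test_that("the pattern screen applies the four-threshold rule", {
  mk <- function(a, b, gene, d) tibble::tibble(sample_a = a, sample_b = b,
                                               comparison = paste0(a, "-", b),
                                               gene_id = gene, d = d,
                                               n_a = 100L, n_b = 100L)
  cmp <- dplyr::bind_rows(
    mk("wt", "C30G", "g1", 0.05), mk("oxt6", "C30GM", "g1", 0.08),
    mk("wt", "C30GM", "g1", 0.7), mk("wt", "oxt6", "g1", 0.75),
    mk("wt", "C30G", "g2", 0.05), mk("oxt6", "C30GM", "g2", 0.08),
    mk("wt", "C30GM", "g2", 0.1), mk("wt", "oxt6", "g2", 0.75))
  hits <- screen_pattern_genes(cmp, low_thr = 0.2, high_thr = 0.5)
  expect_equal(hits$gene_id, "g1")
  expect_error(screen_pattern_genes(cmp, low_thr = 0.5, high_thr = 0.2),
               "low_thr")
})

test_that("the screen recovers planted retained-shift genes and only those", {
  # genes where C30GM retains the oxt6 usage are the screen's targets; with
  # full restoration the screen comes back empty
  cfg <- tiny_config(seed = 55, planted_screen_fraction = 0.2,
                     planted_apa_fraction = 0.1)
  ref <- generate_reference(cfg)
  prof <- profiles_from_truth(ref, depth_factor = 2, seed = 3)
  cmp <- compare_all_pairs(prof)
  hits <- screen_pattern_genes(cmp, low_thr = 0.25, high_thr = 0.4)
  planted <- sort(ref$truth$genes$gene_id[ref$truth$genes$planted_screen])
  expect_equal(sort(hits$gene_id), planted)

  cfg0 <- tiny_config(seed = 56, planted_screen_fraction = 0,
                      planted_apa_fraction = 0.1)
  ref0 <- generate_reference(cfg0)
  prof0 <- profiles_from_truth(ref0, depth_factor = 2, seed = 4)
  hits0 <- screen_pattern_genes(compare_all_pairs(prof0),
                                low_thr = 0.25, high_thr = 0.4)
  expect_equal(nrow(hits0), 0)
})

test_that("comparison sets carry tidy, glance and curve views", {
  ref <- generate_reference(tiny_config(seed = 61))
  prof <- profiles_from_truth(ref, depth_factor = 1, seed = 5)
  cmp <- compare_all_pairs(prof)
  expect_s3_class(tidy(cmp), "tbl_df")
  g <- glance(cmp)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_comparisons, choose(4, 2))
  curves <- comparison_curves(cmp)
  expect_true(all(c("comparison", "threshold", "cumulative_fraction") %in%
                    names(curves)))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
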