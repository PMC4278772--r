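# two plus-strand genes on one chromosome; tags are drawn in mRNA sense
# ending at a chosen cleavage position (database coordinate)
make_map_fixture <- function(seed = 42) {
  genome <- random_genome(4000, seed = seed)
  ann <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                        start = c(200, 2200), end = c(500, 2500),
                        strand = "+")
  build_extended_utr_db(ann, genome)
}

test_that("a unique exact tag maps with zero mismatches at its junction", {
  db <- make_map_fixture()
  tag <- sense_tag(db, 1, j = 300, L = 50)
  hit <- map_tags(as_read_tbl(tag), db)
  expect_equal(hit$map_status, "mapped")
  expect_equal(hit$gene_id, "gA")
  expect_equal(hit$db_pos, 300)
  expect_equal(hit$mismatches, 0L)
  # genomic cleavage coordinate round-trips through the record map
  expect_equal(hit$position, db_to_genome(db, "gA", 300)$position)
})

test_that("mismatch budget and tie rules are enforced", {
  db <- make_map_fixture()
  tag <- sense_tag(db, 1, j = 300, L = 50)
  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  two <- mutate_at(tag, c(5, 25))
  three <- mutate_at(tag, c(5, 25, 45))
  hits <- map_tags(as_read_tbl(c(two, three)), db, max_mismatch = 2)
  expect_equal(hits$map_status, c("mapped", "unmapped"))
  expect_equal(hits$mismatches[1], 2L)

  # a tag present identically in two records is multimapped
  shared <- strrep("ACGTC", 10)
  genome2 <- random_genome(4000, seed = 9)
  g <- genome2[["chr1"]]
  substr(g, 301, 350) <- shared
  substr(g, 2301, 2350) <- shared
  db2 <- build_extended_utr_db(
    tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                   start = c(200, 2200), end = c(500, 2500), strand = "+"),
    c(chr1 = g))
  hit <- map_tags(as_read_tbl(shared), db2)
  expect_equal(hit$map_status, "multimapped")

  # shorter than the seed length: unmapped
  short <- map_tags(as_read_tbl(substr(tag, 1, 10)), db)
  expect_equal(short$map_status, "unmapped")
})

test_that("site clustering groups nearby positions and conserves tag mass", {
  hits <- tibble::tibble(
    gene_id = "g1", sample = "s1",
    position = c(rep(100, 10), rep(102, 5)),
    map_status = "mapped")
  prof <- build_site_profiles(hits, cluster_window = 24)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$count, 15)
  expect_equal(prof$usage, 1.0)
  expect_equal(prof$site, 100)  # modal position

  hits2 <- tibble::tibble(
    gene_id = "g1", sample = "s1",
    position = c(rep(100, 10), rep(200, 5)),
    map_status = "mapped")
  prof2 <- build_site_profiles(hits2, cluster_window = 24)
  expect_equal(prof2$usage, c(2 / 3, 1 / 3))
  expect_equal(prof2$site, c(100, 200))
})

test_that("clustering conserves per-gene totals on random profiles", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(5:200, 1)
      hits <- tibble::tibble(
        gene_id = sample(c("g1", "g2", "g3"), n, replace = TRUE),
        sample = sample(c("s1", "s2"), n, replace = TRUE),
        position = sample(1:300, n, replace = TRUE),
        map_status = "mapped")
      prof <- build_site_profiles(hits, cluster_window = 24)
      got <- prof |>
        dplyr::group_by(gene_id, sample) |>
        dplyr::summarise(n = sum(count), u = sum(usage), .groups = "drop") |>
        dplyr::arrange(gene_id, sample)
      # brute-force recount, independent of the clustering path
      want <- as.data.frame(table(hits$gene_id, hits$sample))
      want <- want[want$Freq > 0, ]
      want <- want[order(want$Var1, want$Var2), ]
      expect_equal(got$n, want$Freq)
      expect_true(all(abs(got$u - 1) < 1e-12))
    }
  })
})

test_that("error-free synthetic tags map to their true cleavage sites", {
  cfg <- tiny_config(seed = 41, error_rate = 0)
  ref <- generate_reference(cfg)
  sim <- simulate_tag_reads(ref)
  dm <- dplyr::filter(demultiplex(sim$reads, cfg$barcode_table),
                      sample != "unassigned")
  tr <- trim_tags(dm, cfg$adapter_5p, cfg$adapter_3p)
  hits <- map_tags(tr, ref |>
                     (\(r) build_extended_utr_db(r$annotation, r$genome))())
  j <- dplyr::inner_join(dplyr::filter(hits, map_status == "mapped"),
                         sim$read_info, by = "read_id")
  expect_true(all(j$gene_id.x == j$gene_id.y))
  # tags with A-free 3' ends recover the emitted junction exactly; tags whose
  # genuine 3' sequence merges into the remnant run are clipped by a few nt
  expect_gt(mean(j$position == j$junction_genomic), 0.5)
  expect_gt(mean(abs(j$position - j$junction_genomic) <=
                   3 * cfg$cluster_sigma), 0.999)
  truth_sites <- dplyr::left_join(
    j, ref$truth$sites,
    by = c("gene_id.y" = "gene_id", "site" = "site"))
  expect_gt(mean(abs(truth_sites$position - truth_sites$genomic_pos) <=
                   3 * cfg$cluster_sigma), 0.98)
})
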