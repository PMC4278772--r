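#' Demultiplex multiplexed tag reads by barcode
#'
#' Assigns each read to the unique sample whose barcode is within
#' `max_mismatch` substitutions of the read's leading bases, and removes the
#' barcode from assigned reads. Reads matching no barcode, or equidistant from
#' two or more barcodes at the minimum distance, are labelled `"unassigned"`
#' (and left untrimmed). Every input read appears in exactly one output class,
#' so `nrow(input)` always equals assigned plus unassigned.
#'
#' @param reads Tibble with columns `read_id`, `sequence` and `quality`.
#' @param barcode_table Tibble with columns `sample` and `barcode`
#'   (equal-length, pairwise distinct barcodes); extra columns such as
#'   `genotype` are carried along by downstream joins.
#' @param max_mismatch Maximum substitutions tolerated in the barcode
#'   (default 0, exact matching).
#' @return The input tibble with a `sample` column added; for assigned reads
#'   `sequence` and `quality` have the barcode removed.
#' @export
#' @examples
#' reads <- tibble::tibble(read_id = "r1", sequence = "ACGTACGGGTTT",
#'                         quality = strrep("I", 12))
#' bc <- tibble::tibble(sample = c("a", "b"), barcode = c("ACGTAC", "TGCAGT"))
#' demultiplex(reads, bc)$sample
demultiplex <- function(reads, barcode_table, max_mismatch = 0) {
  stopifnot(is.data.frame(reads), is.data.frame(barcode_table))
  bc <- barcode_table$barcode
  if (anyDuplicated(bc)) stop("duplicate barcodes in barcode table")
  if (anyDuplicated(barcode_table$sample)) stop("duplicate sample labels")
  bl <- unique(nchar(bc))
  if (length(bl) != 1) stop("barcodes must be equal length")
  if (max_mismatch >= bl) stop("max_mismatch must be smaller than the barcode length")

  prefix <- substr(reads$sequence, 1L, bl)
  d <- matrix(0L, nrow = nrow(reads), ncol = length(bc))
  for (i in seq_len(bl)) {
    ch <- substr(prefix, i, i)
    for (j in seq_along(bc)) {
      d[, j] <- d[, j] + (ch != substr(bc[j], i, i))
    }
  }
  dmin <- do.call(pmin, c(as.data.frame(d), list(na.rm = TRUE)))
  nbest <- rowSums(d == dmin)
  hit <- dmin <= max_mismatch & nbest == 1L
  best <- max.col(-d, ties.method = "first")
  out <- reads
  out$sample <- ifelse(hit, barcode_table$sample[best], "unassigned")
  out$sequence <- ifelse(hit, substr(reads$sequence, bl + 1L, nchar(reads$sequence)),
                         reads$sequence)
  out$quality <- ifelse(hit, substr(reads$quality, bl + 1L, nchar(reads$quality)),
                        reads$quality)
  as_tibble(out)
}

#' Summarize a demultiplexing run
#'
#' @param reads Tibble returned by [demultiplex()].
#' @return Tibble with per-sample read counts (including `"unassigned"`).
#' @export
demux_report <- function(reads) {
  dplyr::count(reads, .data$sample, name = "reads")
}

#' Trim demultiplexed reads to bare poly(A) tags
#'
#' Removes, in order: a leading 5' adapter (exact prefix match), everything
#' from the first occurrence of the 3' sequencing adapter onwards, and the
#' terminal oligo-dT remnant, defined as the maximal terminal A-run with at
#' most one non-A interruption, stripped only when it contains at least
#' `a_min` A's (this distinguishes a primer remnant from genuinely A-rich 3'
#' sequence). Results shorter than `min_len` are flagged `"discarded"`.
#' Trimming is idempotent: a trimmed tag passes through unchanged.
#'
#' @param reads Tibble with columns `sequence` and `quality` (plus any
#'   pass-through columns, e.g. `sample` from [demultiplex()]).
#' @param adapter_5p,adapter_3p Non-empty adapter sequences.
#' @param min_len Minimum tag length retained (default 20 nt).
#' @param a_min Minimum number of A's for the terminal run to be treated as an
#'   oligo-dT remnant (default 5).
#' @return The input tibble with `sequence`/`quality` replaced by the trimmed
#'   tag and a `status` column (`"trimmed"` or `"discarded"`).
#' @export
#' @examples
#' r <- tibble::tibble(sequence = paste0("AGCTGACT", strrep("CGTA", 7), "AAAAAA"),
#'                     quality = strrep("I", 42))
#' trim_tags(r, "AGCTGACT", "AGATCGGAAGAGC")$sequence
trim_tags <- function(reads, adapter_5p, adapter_3p, min_len = 20, a_min = 5) {
  stopifnot(nzchar(adapter_5p), nzchar(adapter_3p), min_len >= 0)
  seq <- reads$sequence
  qual <- reads$quality
  n5 <- nchar(adapter_5p)

  has5 <- startsWith(seq, adapter_5p)
  start <- ifelse(has5, n5 + 1L, 1L)
  s <- substr(seq, start, nchar(seq))

  pos3 <- regexpr(adapter_3p, s, fixed = TRUE)
  end <- ifelse(pos3 > 0L, pos3 - 1L, nchar(s))
  s <- substr(s, 1L, end)

  # terminal A-run with at most one interruption, e.g. ...AAAAGAAA
  m <- regexpr("A+([^A]A+)?$", s, perl = TRUE)
  ml <- attr(m, "match.length")
  run <- ifelse(m > 0L, substr(s, m, m + ml - 1L), "")
  n_a <- nchar(run) - grepl("[^A]", run)
  cut <- m > 0L & n_a >= a_min
  s <- ifelse(cut, substr(s, 1L, m - 1L), s)

  out <- reads
  out$sequence <- s
  out$quality <- substr(qual, start, start + nchar(s) - 1L)
  out$status <- ifelse(nchar(s) >= min_len, "trimmed", "discarded")
  as_tibble(out)
}
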