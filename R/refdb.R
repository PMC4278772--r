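#' Build the extended, reverse-complemented 3'-UTR mapping database
#'
#' Constructs one database record per annotated 3'-UTR: the UTR is extended at
#' its 3' end by up to `extension` nucleotides downstream (strand-aware,
#' truncated at chromosome ends) and the stored sequence is the reverse
#' complement of the genomic-sense extended UTR. The extension improves
#' recovery of tags from transcripts with inefficient termination; the reverse
#' complement puts database records in the orientation of first-strand cDNA,
#' so the 3'-most base of the extended region sits at database position 0.
#'
#' Coordinates are 0-based half-open throughout the package; GFF3/BED
#' conversion happens at the I/O boundary (see [read_utr_annotation()]).
#' Extensions are not truncated at neighbouring genes; overlapping records are
#' permitted and resolved at mapping time by the unique-best-hit rule.
#'
#' @param annotation Tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open UTR interval) and `strand` (`"+"` or `"-"`).
#' @param genome Named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param extension Nucleotides of downstream extension (default 500).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `utr_start`, `utr_end`, `span_start`, `span_end` (genomic span of the
#'   extended region), `extension_realized`, `db_length` and `db_seq`.
#' @export
#' @examples
#' genome <- c(chr1 = strrep("ACGT", 500))
#' ann <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                       start = 1000, end = 1200, strand = "+")
#' db <- build_extended_utr_db(ann, genome)
#' db$db_length  # 700 = 200-nt UTR + 500-nt extension
build_extended_utr_db <- function(annotation, genome, extension = 500) {
  stopifnot(is.data.frame(annotation), extension >= 0)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(annotation))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) stop("genome sequences must be named")
  unknown <- setdiff(unique(annotation$chrom), names(genome))
  if (length(unknown) > 0) {
    stop("gene on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  chrlen <- setNames(nchar(genome), names(genome))
  ann <- dplyr::mutate(annotation, .chrlen = chrlen[.data$chrom])
  bad <- ann$start < 0 | ann$end > ann$.chrlen | ann$start >= ann$end
  if (any(bad)) {
    stop("UTR interval empty or outside chromosome for: ",
         paste(ann$gene_id[bad], collapse = ", "))
  }
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  plus <- ann$strand == "+"
  span_start <- ifelse(plus, ann$start, pmax(ann$start - extension, 0))
  span_end <- ifelse(plus, pmin(ann$end + extension, ann$.chrlen), ann$end)
  ext_real <- ifelse(plus, span_end - ann$end, ann$start - span_start)
  raw <- substring(genome[ann$chrom], span_start + 1, span_end)
  db_seq <- ifelse(plus, revcomp(raw), raw)
  tibble(
    gene_id = ann$gene_id, chrom = ann$chrom, strand = ann$strand,
    utr_start = ann$start, utr_end = ann$end,
    span_start = span_start, span_end = span_end,
    extension_realized = ext_real,
    db_length = span_end - span_start,
    db_seq = unname(db_seq)
  )
}

#' Map database positions back to genomic coordinates
#'
#' Database position 0 is the 3'-most base of the extended region; positions
#' increase towards the 5' end of the UTR. `db_to_genome()` and
#' `genome_to_db()` are exact inverses on every record.
#'
#' @param db Database tibble from [build_extended_utr_db()].
#' @param gene_id Character vector of gene identifiers (recycled against
#'   `db_position`).
#' @param db_position Integer vector of 0-based database positions.
#' @return For `db_to_genome()`, a tibble with `gene_id`, `chrom`, `position`
#'   (0-based genomic coordinate) and `strand`; for `genome_to_db()`, a tibble
#'   with `gene_id` and `db_position`.
#' @export
db_to_genome <- function(db, gene_id, db_position) {
  i <- match(gene_id, db$gene_id)
  if (anyNA(i)) stop("unknown gene_id: ",
                     paste(unique(gene_id[is.na(i)]), collapse = ", "))
  if (any(db_position < 0 | db_position >= db$db_length[i])) {
    stop("db_position out of range [0, db_length)")
  }
  plus <- db$strand[i] == "+"
  tibble(
    gene_id = gene_id,
    chrom = db$chrom[i],
    position = ifelse(plus, db$span_end[i] - 1 - db_position,
                      db$span_start[i] + db_position),
    strand = db$strand[i]
  )
}

#' @rdname db_to_genome
#' @param genomic_position Integer vector of 0-based genomic coordinates
#'   within the record's extended span.
#' @export
genome_to_db <- function(db, gene_id, genomic_position) {
  i <- match(gene_id, db$gene_id)
  if (anyNA(i)) stop("unknown gene_id: ",
                     paste(unique(gene_id[is.na(i)]), collapse = ", "))
  if (any(genomic_position < db$span_start[i] |
          genomic_position >= db$span_end[i])) {
    stop("genomic_position outside the record's extended span")
  }
  plus <- db$strand[i] == "+"
  tibble(
    gene_id = gene_id,
    db_position = ifelse(plus, db$span_end[i] - 1 - genomic_position,
                         genomic_position - db$span_start[i])
  )
}
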