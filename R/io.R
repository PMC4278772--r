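#' Read and write FASTQ read sets
#'
#' Thin tibble adapters around [Biostrings] FASTQ support (Phred+33).
#'
#' @param path File path.
#' @return `read_fastq()` returns a tibble with `read_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(read_id = names(x),
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read and write genome FASTA
#'
#' @param path File path.
#' @return `read_genome_fasta()` returns a named character vector of
#'   chromosome sequences (names truncated at the first whitespace).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read and write 3'-UTR annotation (GFF3 or BED)
#'
#' Internally the package uses 0-based half-open intervals; conversion
#' to/from GFF3's 1-based closed convention happens here (BED is already
#' 0-based half-open, handled by [rtracklayer]).
#'
#' @param path File path; format guessed from the extension unless given.
#' @param format `"gff3"` or `"bed"`.
#' @return `read_utr_annotation()` returns a tibble `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_utr_annotation <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3")
  gr <- rtracklayer::import(path, format = format)
  meta <- S4Vectors::mcols(gr)
  gene_id <- meta$ID %||% meta$Name %||% meta$name %||% meta$gene_id
  if (is.null(gene_id)) stop("no gene identifier column in ", path)
  tibble(gene_id = as.character(gene_id),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)))
}

#' @rdname read_utr_annotation
#' @param annotation UTR tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @export
write_utr_annotation <- function(annotation, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = annotation$strand)
  if (format == "gff3") {
    S4Vectors::mcols(gr)$ID <- annotation$gene_id
    S4Vectors::mcols(gr)$type <- "three_prime_UTR"
    S4Vectors::mcols(gr)$source <- "patseq"
  } else {
    S4Vectors::mcols(gr)$name <- annotation$gene_id
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Write the mapping database as FASTA plus a coordinate-map sidecar
#'
#' @param db Database tibble from [build_extended_utr_db()].
#' @param fasta_path,map_path Output paths for the record sequences and the
#'   TSV coordinate map.
#' @export
write_utr_db <- function(db, fasta_path, map_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(db$db_seq, db$gene_id)), fasta_path)
  readr::write_tsv(dplyr::select(db, -"db_seq"), map_path)
  invisible(fasta_path)
}

#' Export mapped tags as SAM
#'
#' One record per mapped tag, aligned against the database sequences (the
#' stored SEQ is the tag as aligned, i.e. reverse-complemented into database
#' orientation). Unmapped and multimapped tags are not emitted.
#'
#' @param hits Tibble from [map_tags()] (must retain the `sequence` column).
#' @param db Database tibble the tags were mapped against.
#' @param path Output path.
#' @export
write_sam <- function(hits, db, path) {
  mapped <- dplyr::filter(hits, .data$map_status == "mapped")
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", db$gene_id, db$db_length),
    "@PG\tID:patseq\tPN:patseq")
  if (nrow(mapped) > 0) {
    ids <- mapped$read_id %||% sprintf("tagrow%07d", seq_len(nrow(mapped)))
    recs <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                    ids, mapped$gene_id, mapped$db_pos + 1L,
                    nchar(mapped$sequence), revcomp(mapped$sequence),
                    mapped$mismatches)
  } else {
    recs <- character()
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
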