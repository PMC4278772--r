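#' Build a k-mer seed index over a UTR database
#'
#' Indexes every overlapping k-mer (2-bit encoded) of every database record.
#' The index is an external pointer valid for the current session; rebuild it
#' rather than serializing it.
#'
#' @param db Database tibble from [build_extended_utr_db()].
#' @param k Seed length in nt (default 16).
#' @return A list of class `"pat_tag_index"` wrapping the index pointer.
#' @export
build_tag_index <- function(db, k = 16) {
  stopifnot(is.data.frame(db), "db_seq" %in% names(db))
  structure(list(ptr = build_seed_index_cpp(db$db_seq, as.integer(k)),
                 k = as.integer(k), n_records = nrow(db)),
            class = "pat_tag_index")
}

#' Align trimmed tags to the extended-UTR database
#'
#' Tags are sequenced in mRNA sense and end at the cleavage site, while
#' database records are stored in first-strand cDNA orientation (reverse
#' complement of the extended UTR); each tag is therefore reverse-complemented
#' before seeding, which is equivalent to sense alignment against the
#' database. Alignment uses exact k-mer seeds at three offsets followed by
#' full-length verification allowing at most `max_mismatch` substitutions (no
#' indels). The unique lowest-mismatch hit is reported; ties across distinct
#' loci give `"multimapped"`, tags shorter than the seed or with no
#' acceptable hit give `"unmapped"`.
#'
#' The cleavage coordinate of a mapped tag is the database position of the
#' tag base adjacent to the removed poly(A) remnant, i.e. the start of the
#' reverse-complemented alignment; it is also reported in genomic coordinates
#' via the record's coordinate map.
#'
#' @param tags Tibble with a `sequence` column (trimmed tags; rows flagged
#'   `"discarded"` by [trim_tags()] are passed through unmapped). All other
#'   columns are carried along.
#' @param db Database tibble from [build_extended_utr_db()].
#' @param max_mismatch Substitution budget (default 2).
#' @param k Seed length (default 16).
#' @param index Optional prebuilt [build_tag_index()] over `db`.
#' @return The input tibble plus `map_status` (`"mapped"`, `"unmapped"`,
#'   `"multimapped"`), `gene_id`, `db_pos` (cleavage position in database
#'   coordinates), `mismatches`, `chrom`, `position` (genomic cleavage
#'   coordinate, 0-based) and `strand`.
#' @export
map_tags <- function(tags, db, max_mismatch = 2, k = 16, index = NULL) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  if (is.null(index)) index <- build_tag_index(db, k)
  stopifnot(inherits(index, "pat_tag_index"), index$k == k)
  res <- map_tags_cpp(tags$sequence, db$db_seq, index$ptr,
                      as.integer(k), as.integer(max_mismatch), TRUE)
  status <- c("mapped", "unmapped", "multimapped", "unmapped")[res$status + 1L]
  if ("status" %in% names(tags)) {
    status[tags$status == "discarded"] <- "unmapped"
    res$record[tags$status == "discarded"] <- NA_integer_
  }
  out <- tags
  out$map_status <- status
  out$gene_id <- db$gene_id[res$record]
  # rc(tag) starts at the junction base, so the alignment start IS the
  # cleavage position in database coordinates
  out$db_pos <- ifelse(status == "mapped", res$start, NA_integer_)
  out$mismatches <- ifelse(status == "mapped", res$mismatches, NA_integer_)
  plus <- db$strand[res$record] == "+"
  out$chrom <- ifelse(status == "mapped", db$chrom[res$record], NA_character_)
  out$position <- ifelse(status == "mapped",
                         ifelse(plus, db$span_end[res$record] - 1L - out$db_pos,
                                db$span_start[res$record] + out$db_pos),
                         NA_integer_)
  out$strand <- ifelse(status == "mapped", db$strand[res$record], NA_character_)
  as_tibble(out)
}

# single-linkage 1-d clustering: sorted positions chain while successive
# gaps are <= w; returns a cluster id per element of `pos` (any order)
cluster_positions <- function(pos, w) {
  ord <- order(pos)
  sorted <- pos[ord]
  cl_sorted <- cumsum(c(1L, diff(sorted) > w))
  cl <- integer(length(pos))
  cl[ord] <- cl_sorted
  cl
}

#' Aggregate mapped tags into per-gene poly(A)-site profiles
#'
#' Clusters cleavage positions within each gene and sample by single linkage:
#' positions within `cluster_window` of any cluster member join the cluster.
#' Each cluster is represented by its modal position (ties broken towards the
#' smaller coordinate) and carries the cluster tag count and the usage
#' proportion (cluster count over the gene's total in that sample). Clustered
#' counts always sum to the gene's raw mapped-tag total.
#'
#' @param hits Tibble from [map_tags()] with a `sample` column; only rows
#'   with `map_status == "mapped"` contribute.
#' @param cluster_window Single-linkage window in nt (default 24, the usual
#'   scale of cleavage microheterogeneity).
#' @return Tibble with `gene_id`, `sample`, `site` (representative genomic
#'   position), `count` and `usage`.
#' @export
build_site_profiles <- function(hits, cluster_window = 24) {
  stopifnot(all(c("gene_id", "sample", "position") %in% names(hits)))
  mapped <- dplyr::filter(hits, .data$map_status == "mapped")
  if (nrow(mapped) == 0) {
    return(tibble(gene_id = character(), sample = character(),
                  site = integer(), count = integer(), usage = double()))
  }
  per_pos <- dplyr::count(mapped, .data$sample, .data$gene_id, .data$position,
                          name = "n")
  per_pos <- dplyr::arrange(per_pos, .data$sample, .data$gene_id, .data$position)
  grp_change <- c(TRUE, per_pos$sample[-1] != per_pos$sample[-nrow(per_pos)] |
                    per_pos$gene_id[-1] != per_pos$gene_id[-nrow(per_pos)])
  gap <- c(0L, diff(per_pos$position))
  per_pos$cluster <- cumsum(grp_change | gap > cluster_window)
  out <- per_pos |>
    dplyr::group_by(.data$sample, .data$gene_id, .data$cluster) |>
    dplyr::summarise(
      site = .data$position[order(-.data$n, .data$position)][1],
      count = sum(.data$n), .groups = "drop_last") |>
    dplyr::mutate(usage = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "sample", "site", "count", "usage") |>
    dplyr::arrange(.data$gene_id, .data$sample, .data$site)
  out
}
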