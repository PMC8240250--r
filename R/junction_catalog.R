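#' Tabulate splice junctions from aligned reads
#'
#' Collapses the skipped (`N`) intervals of spliced reads into a junction
#' support table. For each distinct skipped interval the table records the
#' number of split reads containing exactly that skip and the number of
#' reads whose aligned genomic span (skips included) intersects the
#' junction interval by at least one base.
#'
#' Junctions extracted from reads are unstranded (`"*"`): read orientation
#' does not determine transcript strand for cDNA protocols. Unstranded
#' junctions match either strand in downstream set operations.
#'
#' @param reads Read tibble from [read_alignments()] or [sim_reads()].
#' @param dataset Optional source label (`"cDNA"`, `"dcDNA"`, `"dRNA"`)
#'   recorded in the output.
#' @return A tibble sorted by (`chrom`, `start`, `end`): `chrom`, `start`,
#'   `end`, `strand`, `split_read_count`, `overlapping_read_count`,
#'   `dataset`.
#' @export
extract_junctions <- function(reads, dataset = NA_character_) {
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), split_read_count = integer(),
    overlapping_read_count = integer(), dataset = character()
  )
  if (nrow(reads) == 0) return(empty)
  n_skips <- vapply(reads$skips, nrow, integer(1))
  if (sum(n_skips) == 0) return(empty)
  idx <- rep(seq_len(nrow(reads)), n_skips)
  mat <- do.call(rbind, reads$skips[n_skips > 0])
  per_read <- tibble(
    chrom = reads$chrom[idx],
    start = as.integer(mat[, 1]),
    end = as.integer(mat[, 2])
  ) |>
    # a read contributes one split-read count per distinct skip it contains
    distinct(.data$chrom, .data$start, .data$end, read = idx)
  junctions <- per_read |>
    count(.data$chrom, .data$start, .data$end, name = "split_read_count") |>
    arrange(.data$chrom, .data$start, .data$end)
  junctions$overlapping_read_count <- region_coverage(reads, junctions)
  junctions |>
    mutate(strand = "*", dataset = dataset) |>
    select("chrom", "start", "end", "strand", "split_read_count",
           "overlapping_read_count", "dataset")
}

#' Junctions implied by transcript models
#'
#' The implied introns of each transcript (gaps between consecutive exons),
#' de-duplicated across models. Junctions on opposite strands with equal
#' coordinates are kept distinct.
#'
#' @param exons Exon tibble from [read_annotation()].
#' @return A tibble of distinct junctions: `chrom`, `start`, `end`,
#'   `strand`.
#' @export
transcript_junctions <- function(exons) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character())
  if (nrow(exons) == 0) return(empty)
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(intron_start = .data$end, intron_end = lead(.data$start)) |>
    ungroup() |>
    filter(!is.na(.data$intron_end)) |>
    distinct(.data$chrom, start = .data$intron_start,
             end = .data$intron_end, .data$strand) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Read coverage over genomic intervals
#'
#' Counts, for each interval, the reads whose aligned genomic span
#' intersects it by at least one base. A read that skips exactly the
#' interval still covers it: its span includes the skip. This junction-local
#' count is the coverage quantity thresholded by the detector.
#'
#' @param reads Read tibble from [read_alignments()] or [sim_reads()].
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @return Integer vector of counts, one per interval row.
#' @export
region_coverage <- function(reads, intervals) {
  check_intervals(intervals, what = "coverage")
  if (nrow(intervals) == 0) return(integer(0))
  if (nrow(reads) == 0) return(rep(0L, nrow(intervals)))
  GenomicRanges::countOverlaps(
    intervals_to_granges(intervals),
    reads_to_span_granges(reads),
    minoverlap = 1L
  )
}
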