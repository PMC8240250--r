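#' Relative abundance of junctions in long-read data
#'
#' The long-read estimator of artifact abundance: the number of split
#' reads whose alignment skips exactly the junction interval, divided by
#' the number of reads whose aligned span overlaps the junction interval
#' by at least one base. A junction with zero overlapping reads has an
#' undefined abundance, reported as `NA` (not 0).
#'
#' @param junctions Junction tibble (`chrom`, `start`, `end`).
#' @param reads Read tibble from [read_alignments()] or [sim_reads()].
#' @return The input with `split_read_count`, `overlapping_read_count`
#'   and `relative_abundance` columns appended.
#' @export
relative_abundance <- function(junctions, reads) {
  check_intervals(junctions, what = "junction")
  if (nrow(junctions) == 0) {
    return(mutate(junctions, split_read_count = integer(0),
                  overlapping_read_count = integer(0),
                  relative_abundance = numeric(0)))
  }
  observed <- extract_junctions(reads)
  j <- junctions |>
    left_join(
      observed |> select("chrom", "start", "end", "split_read_count"),
      by = c("chrom", "start", "end")
    ) |>
    mutate(split_read_count = dplyr::coalesce(.data$split_read_count, 0L))
  j$overlapping_read_count <- region_coverage(reads, j)
  j |>
    mutate(relative_abundance = ifelse(
      .data$overlapping_read_count > 0,
      .data$split_read_count / .data$overlapping_read_count,
      NA_real_
    ))
}

#' Match query junctions in an external junction table with outward-shift
#' tolerance
#'
#' Artifact junctions end in repetitive sequence, so the same event can
#' be registered at shifted coordinates in other datasets. An observed
#' junction matches a query when it is an outward enlargement of the
#' query by at most one repeat length on each side
#' (`observed$start = query$start - shift5`,
#' `observed$end = query$end + shift3`, `0 <= shift5, shift3 <= r`) and
#' its length differs from the query length by at most one repeat length.
#' The exact match (shifts 0,0) always qualifies. Inward shifts never do.
#'
#' @param query Stranded-or-not query junction tibble carrying a repeat
#'   length column.
#' @param observed External junction tibble (`chrom`, `start`, `end`,
#'   optional `strand` and `count`).
#' @param repeat_col Name of the repeat-length column in `query`
#'   (default `"repeat_length"`).
#' @return A tibble of matches: the query coordinates (`query_*`), the
#'   observed junction columns, `shift5`, `shift3` and `length_delta`
#'   (observed length minus query length).
#' @export
shifted_junction_match <- function(query, observed,
                                   repeat_col = "repeat_length") {
  check_intervals(query, what = "query")
  check_intervals(observed, what = "observed")
  if (!repeat_col %in% names(query)) {
    abort(sprintf("query table lacks repeat-length column '%s'", repeat_col))
  }
  r_all <- as.integer(query[[repeat_col]])
  if (any(is.na(r_all) | r_all < 0)) abort("repeat lengths must be >= 0")
  qstrand <- rep(if ("strand" %in% names(query)) query$strand else "*",
                 length.out = nrow(query))
  ostrand <- if ("strand" %in% names(observed)) observed$strand else
    rep("*", nrow(observed))
  out <- vector("list", nrow(query))
  for (i in seq_len(nrow(query))) {
    r <- r_all[i]
    qs <- query$start[i]; qe <- query$end[i]
    shift5 <- qs - observed$start
    shift3 <- observed$end - qe
    delta <- (observed$end - observed$start) - (qe - qs)
    ok <- observed$chrom == query$chrom[i] &
      strand_compatible(qstrand[i], ostrand) &
      shift5 >= 0 & shift5 <= r &
      shift3 >= 0 & shift3 <= r &
      abs(delta) <= r
    if (any(ok)) {
      out[[i]] <- dplyr::bind_cols(
        tibble(query_chrom = query$chrom[i], query_start = qs,
               query_end = qe, repeat_length = r),
        observed[ok, , drop = FALSE],
        tibble(shift5 = as.integer(shift5[ok]),
               shift3 = as.integer(shift3[ok]),
               length_delta = as.integer(delta[ok]))
      )
    }
  }
  matches <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (is.null(matches) || nrow(matches) == 0) {
    return(tibble(query_chrom = character(), query_start = integer(),
                  query_end = integer(), repeat_length = integer(),
                  chrom = character(), start = integer(), end = integer(),
                  shift5 = integer(), shift3 = integer(),
                  length_delta = integer()))
  }
  matches
}

#' Mean per-base coverage over a junction region
#'
#' The denominator of the short-read abundance estimator: the arithmetic
#' mean of per-base read coverage across the junction interval. The
#' short-read relative abundance is then the spliced-read count divided
#' by this mean.
#'
#' @param coverage Numeric vector of per-base coverage spanning the
#'   interval (one value per base).
#' @return The mean coverage, a non-negative number.
#' @export
mean_region_coverage <- function(coverage) {
  if (length(coverage) == 0) abort("coverage vector must span the interval")
  if (any(is.na(coverage)) || any(coverage < 0)) {
    abort("coverage values must be non-negative and non-missing")
  }
  mean(coverage)
}

#' Short-read junction abundance
#'
#' Spliced-read support divided by mean per-base coverage over the
#' junction region, the estimator used for short-read junction tables.
#'
#' @param spliced_count Number of spliced reads supporting the junction.
#' @param coverage Per-base coverage vector across the junction region.
#' @return The abundance estimate; `NA` when mean coverage is zero.
#' @export
short_read_abundance <- function(spliced_count, coverage) {
  m <- mean_region_coverage(coverage)
  if (m == 0) return(NA_real_)
  spliced_count / m
}
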