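#' Detector parameters
#'
#' Thresholds for the falsitron filter cascade. The defaults mirror the
#' published screen: a junction must be supported by at least five split
#' reads in the RT-based (cDNA-type) data, lie in a region covered by at
#' least five direct-RNA reads, be absent from the direct-RNA junction
#' set, fall within (or across two adjacent) direct-RNA exons, and lack
#' canonical splice-site dinucleotides.
#'
#' @param min_coverage Minimum cDNA split support and minimum dRNA
#'   coverage (default 5).
#' @param canonical_pairs Donor-acceptor pairs treated as canonical and
#'   excluded, written `"GT-AG"`. The minor `"GC-AG"` donor may be added.
#' @param require_absent_in_drna Require exact absence of the junction
#'   from the direct-RNA junction set (default `TRUE`).
#' @return A `detector_params` list.
#' @export
detector_params <- function(min_coverage = 5L,
                            canonical_pairs = "GT-AG",
                            require_absent_in_drna = TRUE) {
  min_coverage <- as.integer(min_coverage)
  if (is.na(min_coverage) || min_coverage < 1L) {
    abort("min_coverage must be an integer >= 1")
  }
  if (length(canonical_pairs) == 0) {
    abort("canonical_pairs must name at least one donor-acceptor pair")
  }
  if (!all(grepl("^[ACGT]{2}-[ACGT]{2}$", canonical_pairs))) {
    abort("canonical_pairs must look like 'GT-AG'")
  }
  structure(
    list(
      min_coverage = min_coverage,
      canonical_pairs = unique(canonical_pairs),
      require_absent_in_drna = isTRUE(require_absent_in_drna)
    ),
    class = "detector_params"
  )
}

#' Containment of a junction within a single exon (filter 1a)
#'
#' A junction passes when some exon of a direct-RNA transcript model on
#' the same chromosome (and compatible strand) contains it entirely,
#' boundaries included.
#'
#' @param junctions Junction tibble (`chrom`, `start`, `end`, optional
#'   `strand`; `"*"` matches either strand).
#' @param exons Direct-RNA exon tibble from [read_annotation()].
#' @return A tibble aligned with `junctions`: `host_transcript_id` and
#'   `host_strand` (`NA` where no exon contains the junction). Ties are
#'   broken by smallest transcript id.
#' @export
contained_in_exon <- function(junctions, exons) {
  check_intervals(junctions, what = "junction")
  res <- tibble(host_transcript_id = rep(NA_character_, nrow(junctions)),
                host_strand = rep(NA_character_, nrow(junctions)))
  if (nrow(junctions) == 0 || nrow(exons) == 0) return(res)
  jstrand <- if ("strand" %in% names(junctions)) junctions$strand else "*"
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(junctions),
    intervals_to_granges(exons),
    type = "within"
  )
  if (length(hits) == 0) return(res)
  h <- tibble(
    j = S4Vectors::queryHits(hits),
    transcript_id = exons$transcript_id[S4Vectors::subjectHits(hits)],
    strand = exons$strand[S4Vectors::subjectHits(hits)]
  ) |>
    filter(strand_compatible(rep(jstrand, length.out = nrow(junctions))[.data$j],
                             .data$strand)) |>
    arrange(.data$j, .data$transcript_id) |>
    distinct(.data$j, .keep_all = TRUE)
  res$host_transcript_id[h$j] <- h$transcript_id
  res$host_strand[h$j] <- h$strand
  res
}

#' Junction ends residing in two adjacent exons (filter 1b)
#'
#' A junction passes when, for some direct-RNA model with consecutive
#' exons E_i and E_(i+1), its start lies in E_i and its end in E_(i+1).
#' A junction entirely inside one exon belongs to filter 1a, not 1b.
#'
#' @inheritParams contained_in_exon
#' @return As [contained_in_exon()].
#' @export
spans_adjacent_exons <- function(junctions, exons) {
  check_intervals(junctions, what = "junction")
  res <- tibble(host_transcript_id = rep(NA_character_, nrow(junctions)),
                host_strand = rep(NA_character_, nrow(junctions)))
  if (nrow(junctions) == 0 || nrow(exons) == 0) return(res)
  jstrand <- rep(if ("strand" %in% names(junctions)) junctions$strand else "*",
                 length.out = nrow(junctions))
  pairs <- exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(next_start = lead(.data$start), next_end = lead(.data$end)) |>
    ungroup() |>
    filter(!is.na(.data$next_start))
  if (nrow(pairs) == 0) return(res)
  for (i in seq_len(nrow(junctions))) {
    ok <- pairs$chrom == junctions$chrom[i] &
      strand_compatible(jstrand[i], pairs$strand) &
      pairs$start <= junctions$start[i] & junctions$start[i] < pairs$end &
      pairs$next_start < junctions$end[i] & junctions$end[i] <= pairs$next_end
    if (any(ok)) {
      k <- which(ok)[order(pairs$transcript_id[which(ok)])][1]
      res$host_transcript_id[i] <- pairs$transcript_id[k]
      res$host_strand[i] <- pairs$strand[k]
    }
  }
  res
}

#' Splice-site dinucleotides of junctions
#'
#' Extracts the first and last two intronic bases of each junction in
#' transcript orientation: on `+`, donor = the two bases at the junction
#' start and acceptor = the two bases before the junction end; on `-`,
#' the reverse-complement convention.
#'
#' @param junctions Stranded junction tibble (`chrom`, `start`, `end`,
#'   `strand` in `+`/`-`).
#' @param genome Named [Biostrings::DNAStringSet] from [read_genome()].
#' @return The input with `donor_dinucleotide` and `acceptor_dinucleotide`
#'   columns appended.
#' @export
splice_site_dinucleotides <- function(junctions, genome) {
  check_intervals(junctions, require_strand = TRUE, what = "junction")
  if (nrow(junctions) == 0) {
    return(mutate(junctions, donor_dinucleotide = character(0),
                  acceptor_dinucleotide = character(0)))
  }
  if (any(junctions$strand == "*")) {
    abort(paste0("unstranded junction(s): resolve strand from the host ",
                 "transcript before extracting splice-site dinucleotides"))
  }
  donor <- acceptor <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    chrom <- junctions$chrom[i]
    s <- junctions$start[i]
    e <- junctions$end[i]
    len <- seq_length(genome, chrom)
    if (s + 2 > len || e - 2 < 0 || e > len) {
      abort(sprintf("junction %s:%d-%d too close to the sequence edge",
                    chrom, s, e))
    }
    left <- seq_slice(genome, chrom, s, s + 2)
    right <- seq_slice(genome, chrom, e - 2, e)
    if (junctions$strand[i] == "+") {
      donor[i] <- left
      acceptor[i] <- right
    } else {
      donor[i] <- revcomp(right)
      acceptor[i] <- revcomp(left)
    }
  }
  mutate(junctions, donor_dinucleotide = donor, acceptor_dinucleotide = acceptor)
}

#' Detect falsitron candidates from paired cDNA/dRNA evidence
#'
#' Applies the filter cascade that nominates RT-slippage artifact
#' junctions ("falsitrons"): a cDNA-supported junction becomes a
#' candidate iff (i) its split support is at least `min_coverage`; (ii) it
#' is exactly absent from the direct-RNA junction set; (iii) direct-RNA
#' read coverage over the junction interval is at least `min_coverage`;
#' (iv) it is fully contained in a direct-RNA exon (filter path `1a`) or
#' its ends reside in two adjacent direct-RNA exons (filter path `1b`) —
#' 1a is checked first; and (v) its donor-acceptor dinucleotide pair,
#' taken in the host transcript's orientation, is not canonical.
#'
#' @param cdna_junctions Junction support table from [extract_junctions()]
#'   on the cDNA-type reads.
#' @param drna_reads Read tibble of the matched direct-RNA dataset.
#' @param drna_exons Direct-RNA transcript exon tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params A [detector_params()] list.
#' @return A `falsitron_candidates` tibble sorted by coordinate, with the
#'   evidence columns `filter_path`, `host_transcript_id`,
#'   `cdna_split_support`, `drna_coverage`, `donor_dinucleotide`,
#'   `acceptor_dinucleotide` and `relative_abundance`
#'   (split/overlapping in the cDNA data). Per-stage survivor counts are
#'   attached as the `filter_log` attribute and surfaced by [glance()].
#' @export
detect_falsitrons <- function(cdna_junctions, drna_reads, drna_exons, genome,
                              params = detector_params()) {
  stopifnot(inherits(params, "detector_params"))
  check_intervals(cdna_junctions, what = "cDNA junction")
  missing_chrom <- setdiff(
    unique(c(cdna_junctions$chrom, drna_exons$chrom)), names(genome)
  )
  if (length(missing_chrom) > 0) {
    abort(sprintf("chromosome(s) absent from the genome: %s",
                  paste(missing_chrom, collapse = ", ")))
  }

  log <- c(input = nrow(cdna_junctions))
  j <- cdna_junctions |>
    filter(.data$split_read_count >= params$min_coverage)
  log["min_split_support"] <- nrow(j)

  if (params$require_absent_in_drna) {
    drna_junctions <- extract_junctions(drna_reads, dataset = "dRNA")
    j <- j |> anti_join(drna_junctions, by = c("chrom", "start", "end"))
  }
  log["absent_in_drna"] <- nrow(j)

  if (nrow(j) > 0) {
    j$drna_coverage <- region_coverage(drna_reads, j)
    j <- j |> filter(.data$drna_coverage >= params$min_coverage)
  } else {
    j$drna_coverage <- integer(0)
  }
  log["min_drna_coverage"] <- nrow(j)

  host_1a <- contained_in_exon(j, drna_exons)
  host_1b <- spans_adjacent_exons(j, drna_exons)
  j <- j |>
    mutate(
      filter_path = dplyr::case_when(
        !is.na(host_1a$host_transcript_id) ~ "1a",
        !is.na(host_1b$host_transcript_id) ~ "1b",
        TRUE ~ NA_character_
      ),
      host_transcript_id = dplyr::coalesce(host_1a$host_transcript_id,
                                           host_1b$host_transcript_id),
      strand = dplyr::coalesce(host_1a$host_strand, host_1b$host_strand)
    ) |>
    filter(!is.na(.data$filter_path))
  log["within_drna_exons"] <- nrow(j)

  j <- splice_site_dinucleotides(j, genome) |>
    filter(!paste0(.data$donor_dinucleotide, "-", .data$acceptor_dinucleotide)
           %in% params$canonical_pairs)
  log["non_canonical"] <- nrow(j)

  out <- j |>
    mutate(
      cdna_split_support = .data$split_read_count,
      relative_abundance = ifelse(
        .data$overlapping_read_count > 0,
        .data$split_read_count / .data$overlapping_read_count,
        NA_real_
      )
    ) |>
    select("chrom", "start", "end", "strand", "filter_path",
           "host_transcript_id", "cdna_split_support", "drna_coverage",
           "donor_dinucleotide", "acceptor_dinucleotide",
           "relative_abundance") |>
    arrange(.data$chrom, .data$start, .data$end)
  attr(out, "filter_log") <- log
  attr(out, "params") <- params
  class(out) <- c("falsitron_candidates", class(out))
  out
}

#' @export
tidy.falsitron_candidates <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "filter_log") <- NULL
  attr(out, "params") <- NULL
  out
}

#' @export
glance.falsitron_candidates <- function(x, ...) {
  log <- attr(x, "filter_log")
  as_tibble(as.list(log)) |>
    mutate(n_candidates = nrow(x))
}

#' @export
print.falsitron_candidates <- function(x, ...) {
  log <- attr(x, "filter_log")
  cat(sprintf("Falsitron candidates: %d junction(s)\n", nrow(x)))
  if (!is.null(log)) {
    cat("Filter cascade: ",
        paste(sprintf("%s=%d", names(log), log), collapse = " -> "),
        "\n", sep = "")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' Plot candidate abundance by filter path
#'
#' @param object A `falsitron_candidates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.falsitron_candidates <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$end - .data$start,
    y = .data$relative_abundance,
    colour = .data$filter_path
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Falsitron length (nt)",
                  y = "Relative abundance (split / overlapping reads)",
                  colour = "Filter path") +
    ggplot2::theme_minimal()
}
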