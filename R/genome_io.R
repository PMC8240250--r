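#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet].
#' Sequence identifiers are the first whitespace-delimited token of each
#' header; lowercase bases are uppercased. Only `A/C/G/T/N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; empty input yields an empty set.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0) {
    return(Biostrings::DNAStringSet())
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    abort(sprintf("malformed FASTA %s: line 1 does not start with '>': %s",
                  path, first))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA %s: %s", path,
                                      conditionMessage(e))),
    warning = function(w) abort(sprintf("malformed FASTA %s: %s", path,
                                        conditionMessage(w)))
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    abort(sprintf("duplicate sequence id(s) in %s: %s", path,
                  paste(dup, collapse = ", ")))
  }
  up <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(up))
  if (any(bad)) {
    abort(sprintf("sequence(s) with non-ACGTN characters: %s",
                  paste(names(up)[bad], collapse = ", ")))
  }
  up
}

#' Write a genome FASTA file
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read transcript models from GFF3/GTF
#'
#' Imports exon features and groups them into transcript models. File
#' coordinates (1-based inclusive) are converted to the package-internal
#' 0-based half-open convention. Transcript grouping uses the
#' `transcript_id` attribute (GTF) or `Parent` (GFF3); `gene_id` is taken
#' from the exon attributes when present, otherwise from the parent
#' transcript feature.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param format One of `"auto"` (by extension), `"gff3"`, `"gtf"`.
#' @param source_label Optional dataset label attached to every transcript
#'   (e.g. `"cDNA"`, `"dcDNA"`, `"dRNA"`).
#' @return A tibble with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `exon_rank`, `source_label`, sorted
#'   by transcript and genomic start.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf"),
                            source_label = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  empty <- tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    exon_rank = integer(), source_label = character()
  )
  if (file.size(path) == 0) return(empty)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "gtf")
  if (length(gr) == 0) return(empty)
  md <- as.data.frame(S4Vectors::mcols(gr))
  is_exon <- !is.na(md$type) & tolower(as.character(md$type)) == "exon"
  if (!any(is_exon)) return(empty)

  tid <- rep(NA_character_, length(gr))
  if ("transcript_id" %in% names(md)) tid <- as.character(md$transcript_id)
  if ("Parent" %in% names(md)) {
    parent <- vapply(md$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p)[1]
    }, character(1))
    tid <- ifelse(is.na(tid), parent, tid)
  }
  gid <- rep(NA_character_, length(gr))
  if ("gene_id" %in% names(md)) gid <- as.character(md$gene_id)
  # GFF3: recover gene ids from transcript-level features when exons lack one.
  if (any(is.na(gid[is_exon])) && all(c("ID", "Parent") %in% names(md))) {
    is_tx <- !is.na(md$type) &
      tolower(as.character(md$type)) %in% c("mrna", "transcript")
    if (any(is_tx)) {
      tx_parent <- vapply(md$Parent[is_tx], function(p) {
        if (length(p) == 0) NA_character_ else as.character(p)[1]
      }, character(1))
      map <- setNames(tx_parent, as.character(md$ID[is_tx]))
      gid <- ifelse(is.na(gid), unname(map[tid]), gid)
    }
  }

  if (any(is.na(tid[is_exon]) | !nzchar(tid[is_exon]))) {
    bad <- which(is_exon & (is.na(tid) | !nzchar(tid)))
    abort(sprintf("exon record(s) without transcript attribution at index: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }

  exons <- tibble(
    transcript_id = tid[is_exon],
    gene_id = gid[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(BiocGenerics::strand(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    source_label = source_label
  ) |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = row_number()) |>
    ungroup()
  validate_transcript_models(exons)
  exons |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "exon_rank", "source_label")
}

validate_transcript_models <- function(exons) {
  if (nrow(exons) == 0) return(invisible(exons))
  if (any(exons$start < 0 | exons$end <= exons$start)) {
    bad <- exons |> filter(.data$start < 0 | .data$end <= .data$start)
    abort(sprintf("exon(s) violating 0 <= start < end, e.g. %s:%d-%d (%s)",
                  bad$chrom[1], bad$start[1], bad$end[1], bad$transcript_id[1]))
  }
  per_tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      one_chrom = length(unique(.data$chrom)) == 1,
      one_strand = length(unique(.data$strand)) == 1,
      sorted_disjoint = all(diff(.data$start) > 0) &&
        all(utils::head(.data$end, -1) < utils::tail(.data$start, -1) |
              n() == 1),
      .groups = "drop"
    )
  bad <- per_tx |> filter(!.data$one_chrom | !.data$one_strand | !.data$sorted_disjoint)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "transcript(s) with invalid exon chains (overlap, mixed chrom/strand, or zero-length implied intron): %s",
      paste(head(bad$transcript_id, 5), collapse = ", ")
    ))
  }
  invisible(exons)
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per row, converting internal 0-based half-open
#' coordinates back to the 1-based inclusive GTF convention. Round-trips
#' through [read_annotation()].
#'
#' @param exons Exon tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(exons, path) {
  check_intervals(exons, require_strand = TRUE, what = "exon")
  lines <- character(0)
  if (nrow(exons) > 0) {
    gid <- ifelse(is.na(exons$gene_id), exons$transcript_id, exons$gene_id)
    lines <- sprintf(
      '%s\tfalsitronr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      exons$chrom, exons$start + 1L, exons$end, exons$strand,
      gid, exons$transcript_id
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse printed genomic region strings
#'
#' Parses `"chrom:start-end:strand"` strings as printed in publications
#' (1-based, inclusive of both boundary bases) into internal 0-based
#' half-open intervals. Both the ASCII hyphen-minus strand `-` and the
#' typographic minus are accepted.
#'
#' @param text Character vector of region strings.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
parse_region_string <- function(text) {
  text_norm <- gsub("−", "-", text)
  pat <- "^([^:]+):([0-9]+)-([0-9]+):([+-])$"
  ok <- grepl(pat, text_norm)
  if (!all(ok)) {
    abort(sprintf("region string(s) not matching 'chrom:start-end:strand': %s",
                  paste(text[!ok], collapse = ", ")))
  }
  start1 <- as.integer(sub(pat, "\\2", text_norm))
  end1 <- as.integer(sub(pat, "\\3", text_norm))
  if (any(start1 > end1)) {
    abort(sprintf("region start > end in: %s",
                  paste(text[start1 > end1], collapse = ", ")))
  }
  tibble(
    chrom = sub(pat, "\\1", text_norm),
    start = start1 - 1L,
    end = end1,
    strand = sub(pat, "\\4", text_norm)
  )
}

#' Format internal intervals as printed region strings
#'
#' Inverse of [parse_region_string()]: internal 0-based half-open intervals
#' become 1-based inclusive `"chrom:start-end:strand"` strings.
#'
#' @param x Interval tibble with `chrom`, `start`, `end`, `strand`.
#' @return Character vector of region strings.
#' @export
format_region_string <- function(x) {
  check_intervals(x, require_strand = TRUE, what = "region")
  sprintf("%s:%d-%d:%s", x$chrom, x$start + 1L, x$end, x$strand)
}

#' Read spliced long-read alignments
#'
#' Reads SAM or BAM alignments and exposes, per mapped read, the genomic
#' span and the intervals skipped by `N` CIGAR operations (the read's
#' splice junctions). Secondary and supplementary alignments are excluded
#' by default: artifact junctions must come from primary read placements.
#'
#' @param path SAM or BAM file. SAM input is converted with
#'   [Rsamtools::asBam()] on the fly.
#' @param include_secondary Keep secondary/supplementary records too.
#' @return A tibble with one row per mapped read: `read_id`, `chrom`,
#'   `strand` (alignment orientation), `start`, `end` (span, 0-based
#'   half-open, skips included) and `skips`, a list-column of two-column
#'   integer matrices (`start`, `end`) of skipped intervals.
#' @export
read_alignments <- function(path, include_secondary = FALSE) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) abort(sprintf("corrupt SAM %s: %s", path,
                                        conditionMessage(e)))
    )
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (include_secondary) NA else FALSE
  )
  ga <- tryCatch(
    GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flags, what = "qname")
    ),
    error = function(e) abort(sprintf("failed reading alignments from %s: %s",
                                      path, conditionMessage(e)))
  )
  if (length(ga) == 0) {
    return(tibble(
      read_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), skips = list()
    ))
  }
  skip_ranges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga),
    pos = GenomicRanges::start(ga),
    ops = "N"
  )
  skips <- lapply(seq_along(ga), function(i) {
    r <- skip_ranges[[i]]
    cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  tibble(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicRanges::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    start = GenomicRanges::start(ga) - 1L,
    end = GenomicRanges::end(ga),
    skips = skips
  )
}

candidate_columns <- c(
  "chrom", "start", "end", "strand", "filter_path", "host_transcript_id",
  "cdna_split_support", "drna_coverage", "donor_dinucleotide",
  "acceptor_dinucleotide", "repeat_length", "repeat_kmer",
  "relative_abundance"
)

#' Write falsitron candidates to TSV
#'
#' BED-style output: coordinates are 0-based half-open. Missing optional
#' fields (repeat annotation, abundance) are written as `NA`; the
#' abundance is formatted with at least four significant digits.
#'
#' @param candidates Candidate tibble from [detect_falsitrons()] /
#'   [annotate_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- as_tibble(candidates)
  for (col in candidate_columns) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[candidate_columns]
  out$relative_abundance <- ifelse(
    is.na(out$relative_abundance), NA_character_,
    sprintf("%#.4g", as.numeric(out$relative_abundance))
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a candidate or junction TSV
#'
#' Reads BED-style tab-separated tables written by [write_candidates()] or
#' external junction tables (`chrom`, `start`, `end`, `strand`, optional
#' `count` and further columns), keeping 0-based half-open coordinates.
#'
#' @param path Input TSV with a header row.
#' @return A tibble.
#' @export
read_junction_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_intervals(x, what = "junction")
  x
}
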