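coerce_genome <- function(x) {
  if (inherits(x, "DNAStringSet")) x else read_genome(x)
}

coerce_reads <- function(x) {
  if (is.data.frame(x)) x else read_alignments(x)
}

coerce_annotation <- function(x, source_label = NA_character_) {
  if (is.data.frame(x)) x else read_annotation(x, source_label = source_label)
}

#' Run the full falsitron-detection pipeline
#'
#' Orchestrates the analysis end to end: junction extraction from the
#' RT-based (cDNA-type) alignments, the detection filter cascade against
#' the matched direct-RNA evidence, direct-repeat annotation of the
#' candidates, and the splice-site nucleotide profile of the candidate
#' set. Per-stage row counts are reported through [rlang::inform()] and
#' collected in the run log. All inputs may be given as paths (FASTA,
#' SAM/BAM, GFF3/GTF) or as the corresponding in-memory objects.
#'
#' @param cdna_alignments cDNA-type reads: SAM/BAM path or read tibble.
#' @param drna_alignments Direct-RNA reads: SAM/BAM path or read tibble.
#' @param drna_annotation Direct-RNA transcript models: GFF3/GTF path or
#'   exon tibble.
#' @param genome FASTA path or named [Biostrings::DNAStringSet].
#' @param out_dir Optional output directory; when given, writes
#'   `cdna_junctions.tsv`, `candidates.tsv`, `splice_profile.tsv` and
#'   `run_log.txt` (all BED-style, 0-based half-open, deterministic).
#' @param detector A [detector_params()] list.
#' @param repeats A [repeat_params()] list.
#' @param quiet Suppress progress messages.
#' @return A `falsitron_run` list: `candidates` (repeat-annotated),
#'   `cdna_junctions`, `profile`, `log` (named integer vector of stage
#'   counts).
#' @export
run_pipeline <- function(cdna_alignments, drna_alignments, drna_annotation,
                         genome, out_dir = NULL,
                         detector = detector_params(),
                         repeats = repeat_params(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  genome <- coerce_genome(genome)
  cdna_reads <- coerce_reads(cdna_alignments)
  drna_reads <- coerce_reads(drna_alignments)
  drna_exons <- coerce_annotation(drna_annotation, source_label = "dRNA")
  say("inputs: %d cDNA read(s), %d dRNA read(s), %d dRNA exon(s)",
      nrow(cdna_reads), nrow(drna_reads), nrow(drna_exons))

  cdna_junctions <- extract_junctions(cdna_reads, dataset = "cDNA")
  say("junction extraction: %d distinct cDNA junction(s)", nrow(cdna_junctions))

  candidates <- detect_falsitrons(cdna_junctions, drna_reads, drna_exons,
                                  genome, params = detector)
  log <- attr(candidates, "filter_log")
  say("filter cascade: %s",
      paste(sprintf("%s=%d", names(log), log), collapse = " -> "))

  candidates <- annotate_repeats(candidates, genome, params = repeats)
  say("repeat annotation: %d of %d candidate(s) with a >=%d nt direct repeat",
      sum(candidates$repeat_length >= repeats$k_min), nrow(candidates),
      repeats$k_min)

  profile <- splice_profile(tidy_candidate_intervals(candidates), genome)
  log <- c(log, n_candidates = nrow(candidates),
           profiled = attr(profile, "n_sequences"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as_tibble(cdna_junctions),
                     file.path(out_dir, "cdna_junctions.tsv"))
    write_candidates(candidates, file.path(out_dir, "candidates.tsv"))
    readr::write_tsv(as_tibble(profile),
                     file.path(out_dir, "splice_profile.tsv"))
    writeLines(sprintf("%s\t%d", names(log), log),
               file.path(out_dir, "run_log.txt"))
    say("outputs written to %s", out_dir)
  }
  structure(
    list(candidates = candidates, cdna_junctions = cdna_junctions,
         profile = profile, log = log),
    class = "falsitron_run"
  )
}

tidy_candidate_intervals <- function(candidates) {
  as_tibble(candidates) |>
    select("chrom", "start", "end", "strand")
}

#' @export
print.falsitron_run <- function(x, ...) {
  cat("Falsitron pipeline run\n")
  cat("  ", paste(sprintf("%s=%d", names(x$log), x$log), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}
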