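# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open (BED convention); conversion to/from the
# 1-based inclusive convention of FASTA/GFF/GTF/SAM happens only at I/O
# boundaries in genome_io.R.

# Extract genome[chrom][start, end) as an uppercase character string.
seq_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("sequence '%s' not present in the genome", chrom))
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    abort(sprintf(
      "slice [%d,%d) out of bounds for sequence '%s' (length %d)",
      start, end, chrom, len
    ))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start = start + 1, end = end))
}

seq_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    abort(sprintf("sequence '%s' not present in the genome", chrom))
  }
  length(genome[[chrom]])
}

# Reverse complement of plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Strand compatibility: "*" matches either orientation.
strand_compatible <- function(a, b) {
  a == "*" | b == "*" | a == b
}

check_strand <- function(strand, allow_unstranded = TRUE) {
  ok <- strand %in% c("+", "-", if (allow_unstranded) "*")
  if (!all(ok)) {
    abort(sprintf("invalid strand value(s): %s",
                  paste(unique(strand[!ok]), collapse = ", ")))
  }
  invisible(strand)
}

# Validate a junction/interval tibble: chrom, start, end (+ optional strand).
check_intervals <- function(x, require_strand = FALSE, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", if (require_strand) "strand")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s table lacks column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0) || any(x$end <= x$start)) {
      abort(sprintf("%s table violates 0 <= start < end", what))
    }
    if (any(!nzchar(x$chrom))) abort(sprintf("%s table has empty chrom", what))
    if ("strand" %in% names(x)) check_strand(x$strand)
  }
  invisible(x)
}

# GRanges from an internal 0-based half-open tibble (strand dropped: set
# operations that need strand handle it explicitly, because unstranded
# records must match either orientation).
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# Per-read alignment span GRanges (skips count as part of the span).
reads_to_span_granges <- function(reads) {
  intervals_to_granges(reads)
}

# Lower median: for an even count, the lower of the two middle values.
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) return(NA_real_)
  x[ceiling(n / 2)]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
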