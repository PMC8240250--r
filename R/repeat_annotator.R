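#' Repeat-search parameters
#'
#' The direct-repeat search looks for identical k-mers, with k between
#' `k_min` and `k_max`, occurring in a `window`-nt window around each of
#' the two splice sites of a junction, each occurrence overlapping at
#' least one base of its site's boundary dinucleotide motif.
#'
#' @param k_min Smallest repeat length searched (default 4; may be
#'   lowered to 3 to also capture the shortest repeats seen flanking
#'   real artifact loci).
#' @param k_max Largest repeat length searched (default 20).
#' @param window Total window width per splice site, split evenly across
#'   the exon-intron boundary (default 40; must be even).
#' @return A `repeat_params` list.
#' @export
repeat_params <- function(k_min = 4L, k_max = 20L, window = 40L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  window <- as.integer(window)
  if (!(1L <= k_min && k_min <= k_max && k_max <= window)) {
    abort("require 1 <= k_min <= k_max <= window")
  }
  if (window %% 2L != 0L) abort("window width must be even")
  structure(list(k_min = k_min, k_max = k_max, window = window),
            class = "repeat_params")
}

#' Splice-site windows of junctions
#'
#' For each stranded junction, extracts the `window`-nt sequence centred
#' on each splice-site boundary (`window/2` exonic + `window/2` intronic
#' bases), in transcript orientation (minus-strand windows are
#' reverse-complemented). The positions of the boundary dinucleotide
#' motifs within each window are returned alongside: the 5' motif is the
#' first two intronic bases, the 3' motif the last two intronic bases.
#' Windows running off a contig edge are truncated with a warning and the
#' motif positions adjusted.
#'
#' @param junctions Stranded junction tibble.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param window Window width (even; default 40).
#' @return The input with columns `w5`, `w3` (window sequences),
#'   `motif5_lo`, `motif5_hi`, `motif3_lo`, `motif3_hi` (1-based motif
#'   spans within each window) and `truncated`.
#' @export
splice_windows <- function(junctions, genome, window = 40L) {
  check_intervals(junctions, require_strand = TRUE, what = "junction")
  window <- as.integer(window)
  if (window %% 2L != 0L || window < 2L) abort("window width must be even and >= 2")
  half <- window %/% 2L
  n <- nrow(junctions)
  w5 <- w3 <- character(n)
  m5lo <- m5hi <- m3lo <- m3hi <- integer(n)
  truncated <- logical(n)

  # Window around a genomic boundary position b (0-based): [b-half, b+half),
  # clipped to the contig; motif at genomic [mstart, mstart+2).
  window_at <- function(chrom, b, mstart, len) {
    lo <- max(0L, b - half)
    hi <- min(len, b + half)
    seq <- seq_slice(genome, chrom, lo, hi)
    list(seq = seq, lo = lo,
         motif = c(mstart - lo + 1L, mstart + 2L - lo),
         clipped = (lo != b - half) || (hi != b + half))
  }
  flip_motif <- function(motif, width) c(width - motif[2] + 1L, width - motif[1] + 1L)

  for (i in seq_len(n)) {
    chrom <- junctions$chrom[i]
    s <- junctions$start[i]; e <- junctions$end[i]
    len <- seq_length(genome, chrom)
    if (junctions$strand[i] == "+") {
      a5 <- window_at(chrom, s, s, len)       # donor boundary, motif = first 2 intronic
      a3 <- window_at(chrom, e, e - 2L, len)  # acceptor boundary, motif = last 2 intronic
      w5[i] <- a5$seq; w3[i] <- a3$seq
      m5lo[i] <- a5$motif[1]; m5hi[i] <- a5$motif[2]
      m3lo[i] <- a3$motif[1]; m3hi[i] <- a3$motif[2]
    } else {
      f5 <- window_at(chrom, e, e - 2L, len)  # donor is at the genomic end on "-"
      f3 <- window_at(chrom, s, s, len)
      w5[i] <- revcomp(f5$seq); w3[i] <- revcomp(f3$seq)
      mm5 <- flip_motif(f5$motif, nchar(f5$seq))
      mm3 <- flip_motif(f3$motif, nchar(f3$seq))
      m5lo[i] <- mm5[1]; m5hi[i] <- mm5[2]
      m3lo[i] <- mm3[1]; m3hi[i] <- mm3[2]
      a5 <- f5; a3 <- f3
    }
    truncated[i] <- a5$clipped || a3$clipped
  }
  if (any(truncated)) {
    warn(sprintf("%d junction window(s) truncated at a contig edge",
                 sum(truncated)))
  }
  junctions |>
    mutate(w5 = w5, w3 = w3, motif5_lo = m5lo, motif5_hi = m5hi,
           motif3_lo = m3lo, motif3_hi = m3hi, truncated = truncated)
}

# All k-mer start positions in `seq` whose occurrence [p, p+k-1] overlaps
# the motif span [mlo, mhi] by >= 1 base (1-based positions).
motif_overlapping_starts <- function(seq, k, mlo, mhi) {
  L <- nchar(seq)
  if (k > L) return(integer(0))
  lo <- max(1L, mlo - k + 1L)
  hi <- min(L - k + 1L, mhi)
  if (lo > hi) return(integer(0))
  lo:hi
}

#' Largest direct repeat shared between two splice-site windows
#'
#' Finds the largest k in `[k_min, k_max]` such that some k-mer occurs in
#' the 5'-site window overlapping its boundary motif and also occurs in
#' the 3'-site window overlapping that motif. Ties among equal-length
#' k-mers are broken by the smallest total distance of the occurrence
#' centres to their motif centres, then lexicographically.
#'
#' @param w5,w3 Window sequences from [splice_windows()].
#' @param motif5,motif3 Length-2 integer vectors: 1-based motif spans
#'   within `w5` and `w3`.
#' @param params A [repeat_params()] list.
#' @return A one-row tibble: `repeat_length` (0 when no repeat
#'   qualifies), `repeat_kmer`, `repeat_pos5`, `repeat_pos3` (1-based
#'   occurrence starts within the windows), `overlaps_motifs`.
#' @export
max_direct_repeat <- function(w5, w3, motif5, motif3,
                              params = repeat_params()) {
  stopifnot(inherits(params, "repeat_params"))
  if (!nzchar(w5) || !nzchar(w3)) abort("empty splice-site window")
  none <- tibble(repeat_length = 0L, repeat_kmer = NA_character_,
                 repeat_pos5 = NA_integer_, repeat_pos3 = NA_integer_,
                 overlaps_motifs = FALSE)
  c5 <- mean(motif5); c3 <- mean(motif3)
  for (k in seq(params$k_max, params$k_min)) {
    p5 <- motif_overlapping_starts(w5, k, motif5[1], motif5[2])
    p3 <- motif_overlapping_starts(w3, k, motif3[1], motif3[2])
    if (length(p5) == 0 || length(p3) == 0) next
    k5 <- substring(w5, p5, p5 + k - 1L)
    k3 <- substring(w3, p3, p3 + k - 1L)
    shared <- intersect(k5, k3)
    if (length(shared) == 0) next
    best <- NULL
    for (km in shared) {
      o5 <- p5[k5 == km]; o3 <- p3[k3 == km]
      d5 <- abs(o5 + (k - 1) / 2 - c5)
      d3 <- abs(o3 + (k - 1) / 2 - c3)
      cand <- list(kmer = km,
                   pos5 = o5[which.min(d5)], pos3 = o3[which.min(d3)],
                   dist = min(d5) + min(d3))
      if (is.null(best) || cand$dist < best$dist ||
          (cand$dist == best$dist && cand$kmer < best$kmer)) {
        best <- cand
      }
    }
    return(tibble(repeat_length = k, repeat_kmer = best$kmer,
                  repeat_pos5 = best$pos5, repeat_pos3 = best$pos3,
                  overlaps_motifs = TRUE))
  }
  none
}

#' Annotate junctions with flanking direct repeats
#'
#' Runs the splice-site window extraction and the shared-k-mer search on
#' every interval, attaching `repeat_length` (0 when no motif-overlapping
#' shared k-mer of length >= `k_min` exists), `repeat_kmer` and the
#' occurrence positions. Use [repeat_summary()] for the catalogue-level
#' statistics (fraction with a repeat of length >= 4, lower-median repeat
#' length among those).
#'
#' @param intervals Stranded interval/candidate tibble (falsitron
#'   candidates, exitron catalogues, intron sets, ...).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params A [repeat_params()] list.
#' @return The input with repeat-annotation columns appended; class and
#'   attributes of `falsitron_candidates` inputs are preserved.
#' @export
annotate_repeats <- function(intervals, genome, params = repeat_params()) {
  check_intervals(intervals, require_strand = TRUE, what = "interval")
  if (nrow(intervals) == 0) {
    return(mutate(intervals, repeat_length = integer(0),
                  repeat_kmer = character(0), repeat_pos5 = integer(0),
                  repeat_pos3 = integer(0), overlaps_motifs = logical(0)))
  }
  win <- splice_windows(as_tibble(intervals), genome, window = params$window)
  ann <- pmap(
    list(win$w5, win$w3, win$motif5_lo, win$motif5_hi,
         win$motif3_lo, win$motif3_hi),
    function(w5, w3, m5lo, m5hi, m3lo, m3hi) {
      max_direct_repeat(w5, w3, c(m5lo, m5hi), c(m3lo, m3hi), params)
    }
  ) |> list_rbind()
  out <- dplyr::bind_cols(intervals, ann)
  class(out) <- class(intervals)
  attr(out, "filter_log") <- attr(intervals, "filter_log")
  attr(out, "params") <- attr(intervals, "params")
  out
}

#' Summary statistics of a repeat-annotated catalogue
#'
#' @param annotated Output of [annotate_repeats()].
#' @param min_length Repeat length counted as "has a direct repeat"
#'   (default 4).
#' @return One-row tibble: `n`, `n_with_repeat`, `fraction_with_repeat`
#'   (`NA` for an empty catalogue), `median_repeat_length` (lower median
#'   over items with a qualifying repeat), `max_repeat_length`.
#' @export
repeat_summary <- function(annotated, min_length = 4L) {
  stopifnot("repeat_length" %in% names(annotated))
  n <- nrow(annotated)
  with_rep <- annotated$repeat_length[annotated$repeat_length >= min_length]
  tibble(
    n = n,
    n_with_repeat = length(with_rep),
    fraction_with_repeat = if (n == 0) NA_real_ else length(with_rep) / n,
    median_repeat_length = if (length(with_rep) == 0) NA_real_
                           else as.numeric(lower_median(with_rep)),
    max_repeat_length = if (length(with_rep) == 0) NA_integer_
                        else max(with_rep)
  )
}
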